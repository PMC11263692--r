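# Time-tree reading, sibling-tip partitions, SibSwap shuffles and the
# subsampling robustness checks.

quartet <- function() read_timetree("((A:1,B:1):1,(C:1,D:1):1);")

test_that("trees are read with ages measured back from the leaves", {
  tr <- quartet()
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(root_age(tr), 2)
  poly <- read_timetree("(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(poly), 3L)
  expect_error(read_timetree("((A:1,B:-1):1,C:2);"),
               "negative branch lengths")
  expect_error(read_timetree("((A,B),C);"),
               "no branch lengths")
})

test_that("unmatched leaves are reported when a species list is given", {
  expect_warning(tr <- read_timetree("((A:1,B:1):1,C:2);",
                                     species = c("A", "B")),
                 "not in the trait table")
  expect_equal(attr(tr, "unmatched_leaves"), "C")
})

test_that("sibling tips cut the quartet as expected at each level", {
  tr <- quartet()
  p_mid <- sibling_tips(tr, 1.5)
  expect_equal(length(p_mid$groups), 2L)
  expect_setequal(sapply(p_mid$groups, paste, collapse = ""), c("AB", "CD"))
  p_low <- sibling_tips(tr, 0.5)
  expect_equal(lengths(p_low$groups), setNames(rep(1L, 4), paste0("group", 1:4)))
  # node age exactly at the cut: the node's subtree is the group
  p_tie <- sibling_tips(tr, 1)
  expect_equal(length(p_tie$groups), 2L)
  expect_warning(p_all <- sibling_tips(tr, 5), "exceeds the root age")
  expect_equal(length(p_all$groups), 1L)
  expect_setequal(p_all$groups[[1]], c("A", "B", "C", "D"))
  expect_error(sibling_tips(tr, 0), "positive")
})

test_that("partition groups cover all leaves disjointly at any time point", {
  for (s in 1:10) {
    tree <- gen_yule_tree(25, birth_rate = 0.3, seed = 400 + s)
    t <- runif(1, 0.05, 1) * root_age(tree)
    part <- sibling_tips(tree, t)
    all_leaves <- unlist(part$groups)
    expect_equal(msort(all_leaves), msort(tree$tip.label))
    expect_equal(anyDuplicated(all_leaves), 0L)
  }
})

test_that("SibSwap preserves per-group and global trait multisets", {
  tree <- gen_yule_tree(40, seed = 9)
  pts <- gen_brownian_traits(tree, bm_sigma = 1, seed = 10)
  part <- sibling_tips(tree, root_age(tree) * 0.4)
  shuf <- sibswap_shuffle(pts, part, seed = 3)
  expect_equal(msort(shuf[, 1]), msort(pts[, 1]))
  expect_equal(msort(shuf[, 2]), msort(pts[, 2]))
  for (g in part$groups) {
    expect_equal(msort(shuf[g, 1]), msort(pts[g, 1]))
    expect_equal(msort(shuf[g, 2]), msort(pts[g, 2]))
  }
})

test_that("SibSwap with singleton groups is the identity", {
  tr <- quartet()
  pts <- cbind(x = c(1, 2, 3, 4), y = c(5, 6, 7, 8))
  rownames(pts) <- c("A", "B", "C", "D")
  shuf <- sibswap_shuffle(pts, sibling_tips(tr, 0.5), seed = 1)
  expect_equal(shuf, pts)
})

test_that("a single all-species group matches independent shuffling in law", {
  tr <- quartet()
  pts <- cbind(x = c(1, 2, 3, 4), y = c(5, 6, 7, 8))
  rownames(pts) <- c("A", "B", "C", "D")
  part <- suppressWarnings(sibling_tips(tr, 3))
  shuf <- sibswap_shuffle(pts, part, seed = 6)
  expect_equal(msort(shuf[, 1]), msort(pts[, 1]))
  expect_equal(msort(shuf[, 2]), msort(pts[, 2]))
})

test_that("species absent from the partition stay unpermuted with a warning", {
  tr <- quartet()
  pts <- cbind(x = c(1, 2, 3, 4, 9), y = c(5, 6, 7, 8, 9))
  rownames(pts) <- c("A", "B", "C", "D", "Z")
  expect_warning(shuf <- sibswap_shuffle(pts, sibling_tips(tr, 1.5), seed = 2),
                 "absent from the partition")
  expect_equal(shuf["Z", ], pts["Z", ])
})

test_that("tip-averaged points reduce to identity and centroid limits", {
  tr <- quartet()
  pts <- cbind(x = c(0, 2, 4, 6), y = c(1, 3, 5, 7))
  rownames(pts) <- c("A", "B", "C", "D")
  avg_single <- modified_sibswap_points(pts, sibling_tips(tr, 0.5))
  expect_equal(msort(avg_single[, 1]), msort(pts[, 1]))
  avg_all <- modified_sibswap_points(pts, suppressWarnings(sibling_tips(tr, 3)))
  expect_equal(nrow(avg_all), 1L)
  expect_equal(as.numeric(avg_all), unname(colMeans(pts)))
  avg_two <- modified_sibswap_points(pts, sibling_tips(tr, 1.5))
  expect_equal(msort(avg_two[, 1]), c(mean(c(0, 2)), mean(c(4, 6))))
  expect_equal(msort(avg_two[, 2]), c(mean(c(1, 3)), mean(c(5, 7))))
})

test_that("partitions export as species/group TSV", {
  tr <- quartet()
  part <- sibling_tips(tr, 1.5)
  path <- tempfile(fileext = ".tsv")
  write_partition(part, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 4L)
  expect_equal(msort(back$species), c("A", "B", "C", "D"))
  expect_equal(length(unique(back$group_id)), 2L)
})

test_that("the SibSwap curve stays non-significant for Brownian null traits", {
  tree <- gen_yule_tree(150, birth_rate = 0.2, seed = 77)
  pts <- gen_brownian_traits(tree, bm_sigma = 1, seed = 78)
  H <- root_age(tree)
  curve <- sibswap_curve(pts, tree, time_points = H * c(0.7, 0.5, 0.35, 0.1),
                         n_shuffles = 60, n_repeats = 8, seed = 79)
  expect_equal(nrow(curve), 4L)
  expect_true(all(curve$mean_p >= 0 & curve$mean_p <= 1))
  # where groups are large enough to support permutation, p stays above 0.05
  supported <- curve$n_groups < nrow(pts) / 3
  expect_true(any(supported))
  expect_true(all(curve$mean_p[supported] > 0.05))
  expect_true(all(diff(curve$n_groups) >= 0))  # more groups toward the present
  # near-singleton partitions leave no permutation freedom: shuffles tie with
  # the observed cloud and the strict-proportion p collapses toward 0
  expect_lt(curve$mean_p[curve$time == min(curve$time)], 0.05)
})

test_that("class-balanced subsampling is seeded and guards small classes", {
  pts <- gen_triangle_cloud(240, seed = 50)
  classes <- attr(pts, "classes")
  n_min <- min(table(classes))
  r1 <- class_balanced_subsample_test(pts, classes, n_min, n_shuffles = 60, seed = 4)
  r2 <- class_balanced_subsample_test(pts, classes, n_min, n_shuffles = 60, seed = 4)
  expect_identical(attr(r1, "subsample"), attr(r2, "subsample"))
  expect_identical(r1$p_value, r2$p_value)
  expect_error(class_balanced_subsample_test(pts, classes, 10000),
               "fewer than")
})

test_that("fraction 1 reduces to the full-data test and curves are well-formed", {
  pts <- gen_triangle_cloud(200, seed = 51)
  curve <- fraction_subsample_curve(pts, fractions = c(0.5, 1), n_repeats = 4,
                                    n_shuffles = 50, seed = 5)
  expect_equal(curve$n, c(100L, 200L))
  expect_true(all(is.finite(curve$mean_p)))
  full <- curve$mean_p[curve$fraction == 1]
  expect_lt(full, 0.05)   # triangular signal survives at full sampling
  expect_warning(fraction_subsample_curve(pts, fractions = 0.005, n_repeats = 2,
                                          n_shuffles = 10), "fewer than 3")
})
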