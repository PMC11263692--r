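# Phylogeny-aware randomizations: time-sliced sibling-tip partitions,
# SibSwap shuffles, the tip-averaging variant, and sampling-robustness
# experiments on a time-calibrated tree.

#' Read and validate a time-calibrated tree
#'
#' Reads a Newick tree with branch lengths (Mya).  Multifurcations are
#' accepted; branch lengths must be present and non-negative.  If
#' `species` is supplied, leaves not matching any species are reported.
#'
#' @param path Path to a Newick file, a Newick string, or an `ape::phylo`
#'   object.
#' @param species Optional character vector of analysis species.
#' @return An `ape::phylo` tree; attribute `unmatched_leaves` lists leaves
#'   absent from `species` (if given).
#' @export
read_timetree <- function(path, species = NULL) {
  tree <- if (inherits(path, "phylo")) path
  else if (is.character(path) && length(path) == 1L && !file.exists(path) &&
           grepl("\\(", path)) ape::read.tree(text = path)
  else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(species)) {
    unmatched <- setdiff(tree$tip.label, species)
    if (length(unmatched))
      warning(length(unmatched), " tree leaves not in the trait table (excluded from joins)")
    attr(tree, "unmatched_leaves") <- unmatched
  }
  tree
}

# node ages with leaves at age 0 and ages increasing toward the root;
# non-ultrametric trees get tip ages forced to 0 with a warning
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  H <- max(depth[seq_len(ntip)])
  age <- H - depth
  if (any(abs(age[seq_len(ntip)]) > 1e-6 * max(H, 1))) {
    warning("tree is not ultrametric; leaf ages forced to 0")
    age[seq_len(ntip)] <- 0
  }
  age
}

#' Root age of a time-calibrated tree
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return The maximum root-to-leaf path length (Mya).
#' @export
root_age <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Sibling tips: partition the leaves by cutting the tree at a time point
#'
#' Cuts every branch spanning age `t` (leaves at age 0, root at the root
#' age); the leaf set descending from each cut lineage forms one group.
#' Nodes whose age equals `t` exactly head their own group (the cut is
#' closed at the node).  Groups are disjoint and cover all leaves, and
#' partitions at smaller `t` refine partitions at larger `t`.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param t Time point in (0, root age]; values above the root age yield a
#'   single group with a warning.
#' @return An object of class `sibling_partition`: a list with
#'   `time_point` and `groups` (named list of leaf-name vectors).
#' @export
sibling_tips <- function(tree, t) {
  if (t <= 0) stop("time point must be positive")
  age <- node_ages(tree)
  H <- max(age)
  if (t > H * (1 + 1e-12))
    warning("time point ", t, " exceeds the root age ", signif(H, 6),
            "; returning a single group")
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  cut <- age[child] <= t & age[parent] > t
  if (!any(cut)) {
    groups <- list(group1 = tree$tip.label)
  } else {
    heads <- child[cut]
    groups <- lapply(phangorn::Descendants(tree, heads, type = "tips"),
                     function(i) tree$tip.label[i])
    names(groups) <- paste0("group", seq_along(groups))
  }
  structure(list(time_point = t, groups = groups), class = "sibling_partition")
}

#' @export
print.sibling_partition <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("Sibling-tip partition at t = %g: %d groups (sizes %s)\n",
              x$time_point, length(x$groups),
              paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Export a sibling-tip partition as a two-column TSV
#'
#' @param partition A `sibling_partition`.
#' @param path Output path; columns are `species` and `group_id`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(species = unlist(partition$groups, use.names = FALSE),
                   group_id = rep(names(partition$groups),
                                  lengths(partition$groups)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# factor of group membership aligned to `species`; species not covered by
# the partition are excluded from permutation (NA level) with a warning
partition_groups <- function(partition, species) {
  if (is.null(species)) stop("point cloud must carry species row names for SibSwap")
  memb <- rep(NA_character_, length(species))
  for (g in names(partition$groups))
    memb[species %in% partition$groups[[g]]] <- g
  if (anyNA(memb))
    warning(sum(is.na(memb)), " species absent from the partition are left unpermuted")
  factor(memb)
}

#' SibSwap shuffle: permute traits independently within sibling tips
#'
#' Within each group of the partition, permutes the x values and,
#' independently, the y values; assignments across groups are untouched.
#' This preserves both the phylogenetic constraints and the marginal
#' distribution of each trait.
#'
#' @param points A point cloud with species row names.
#' @param partition A `sibling_partition` from [sibling_tips()].
#' @param seed Optional integer seed.
#' @return A shuffled point cloud of the same dimensions.
#' @export
sibswap_shuffle <- function(points, partition, seed = NULL) {
  pts <- as_point_cloud(points)
  if (!is.null(seed)) set.seed(seed)
  .shuffle_within(pts, partition_groups(partition, rownames(pts)))
}

#' SibSwap robustness curve over time points
#'
#' For each time point, repeats the SibSwap triangularity test `n_repeats`
#' times (re-randomizing the null sets each repeat) and summarises the
#' p-values.  Scanning from the oldest time point toward the present, the
#' earliest time point at which the mean p-value significantly exceeds
#' 0.05 (one-sample one-sided t-test) is flagged as the onset of
#' phylogenetic dependence.
#'
#' @param points A point cloud with species row names.
#' @param tree A time-calibrated `ape::phylo` tree.
#' @param time_points Time points (Mya); default: 20 points evenly spaced
#'   from 95% of the root age down to 5%.
#' @param n_shuffles Shuffles per test (default 100).
#' @param n_repeats Repeats per time point (default 100).
#' @param seed Optional integer seed.
#' @return A data frame (class `sibswap_curve`) with columns `time`,
#'   `mean_p`, `sd_p`, `n_groups` and `exceeds_0.05`; attribute
#'   `crossing_time` holds the flagged time point (or `NA`).
#' @export
sibswap_curve <- function(points, tree, time_points = NULL, n_shuffles = 100,
                          n_repeats = 100, seed = NULL) {
  pts <- as_point_cloud(points)
  if (!is.null(seed)) set.seed(seed)
  H <- root_age(tree)
  if (is.null(time_points))
    time_points <- seq(0.95 * H, 0.05 * H, length.out = 20)
  time_points <- sort(time_points, decreasing = TRUE)
  rows <- lapply(time_points, function(t) {
    part <- sibling_tips(tree, t)
    ps <- vapply(seq_len(n_repeats), function(r)
      triangularity_test(pts, n_shuffles = n_shuffles, scheme = "sibswap",
                         partition = part)$p_value, numeric(1))
    exceeds <- if (stats::sd(ps) > 0)
      stats::t.test(ps, mu = 0.05, alternative = "greater")$p.value < 0.05
    else mean(ps) > 0.05
    data.frame(time = t, mean_p = mean(ps), sd_p = stats::sd(ps),
               n_groups = length(part$groups), exceeds_0.05 = exceeds)
  })
  out <- do.call(rbind, rows)
  cross <- out$time[out$exceeds_0.05]
  attr(out, "crossing_time") <- if (length(cross)) max(cross) else NA_real_
  class(out) <- c("sibswap_curve", "data.frame")
  out
}

#' Tip-averaged point cloud for the modified SibSwap test
#'
#' Replaces each sibling-tip group by a single point at the group mean of
#' both traits.  The modified SibSwap test then applies the ordinary
#' triangularity test with independent shuffles to these averaged points.
#'
#' @param points A point cloud with species row names.
#' @param partition A `sibling_partition`.
#' @return A point cloud with one row per non-empty group.
#' @export
modified_sibswap_points <- function(points, partition) {
  pts <- as_point_cloud(points)
  sp <- rownames(pts)
  rows <- lapply(names(partition$groups), function(g) {
    i <- which(sp %in% partition$groups[[g]])
    if (!length(i)) return(NULL)
    colMeans(pts[i, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) message(sum(!keep), " empty sibling-tip group(s) dropped")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(partition$groups)[keep]
  colnames(out) <- c("x", "y")
  out
}

#' Modified SibSwap triangularity test
#'
#' Averages both traits within each sibling-tip group and tests the
#' triangularity of the averaged points against fully shuffled nulls,
#' treating the group means as independent data points.
#'
#' @inheritParams modified_sibswap_points
#' @param n_shuffles,seed Passed to [triangularity_test()].
#' @return A `tratio_result`.
#' @export
modified_sibswap_test <- function(points, partition, n_shuffles = 1000, seed = NULL) {
  avg <- modified_sibswap_points(points, partition)
  if (nrow(avg) < 3L) stop("fewer than 3 averaged points; use a smaller time point")
  triangularity_test(avg, n_shuffles = n_shuffles, scheme = "independent", seed = seed)
}

#' Class-balanced subsampling triangularity test
#'
#' Draws `n_per_class` species from every class without replacement and
#' tests triangularity of the subsample against nulls that permute body
#' mass and sperm length within each class only.
#'
#' @param points A point cloud.
#' @param classes Class labels aligned to rows.
#' @param n_per_class Species drawn per class (typically the smallest
#'   class size).
#' @param n_shuffles,seed Passed to [triangularity_test()].
#' @return A `tratio_result`; attribute `subsample` lists the rows used.
#' @export
class_balanced_subsample_test <- function(points, classes, n_per_class,
                                          n_shuffles = 1000, seed = NULL) {
  pts <- as_point_cloud(points)
  if (length(classes) != nrow(pts)) stop("classes must align with rows")
  if (!is.null(seed)) set.seed(seed)
  classes <- as.factor(classes)
  small <- table(classes) < n_per_class
  if (any(small))
    stop("class(es) with fewer than ", n_per_class, " species: ",
         paste(names(which(small)), collapse = ", "))
  idx <- unlist(lapply(split(seq_len(nrow(pts)), classes),
                       function(i) i[sample.int(length(i), n_per_class)]))
  res <- triangularity_test(pts[idx, , drop = FALSE], n_shuffles = n_shuffles,
                            scheme = "within_class", classes = classes[idx])
  attr(res, "subsample") <- idx
  res
}

#' Fractional subsampling robustness curve
#'
#' For each fraction, repeatedly subsamples that share of the species and
#' runs the triangularity test (SibSwap nulls at `time_point` when a tree
#' is supplied, independent shuffles otherwise), summarising the p-values
#' as mean and standard error across repeats.
#'
#' @param points A point cloud with species row names.
#' @param tree Optional time-calibrated tree for SibSwap nulls.
#' @param fractions Fractions in (0, 1].
#' @param n_repeats Subsamples per fraction (default 30).
#' @param n_shuffles Shuffles per test (default 100).
#' @param time_point Time point for the SibSwap partition; default half
#'   the root age.
#' @param seed Optional integer seed.
#' @return A data frame with `fraction`, `n`, `mean_p`, `se_p`.
#' @export
fraction_subsample_curve <- function(points, tree = NULL, fractions,
                                     n_repeats = 30, n_shuffles = 100,
                                     time_point = NULL, seed = NULL) {
  pts <- as_point_cloud(points)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  part <- NULL
  if (!is.null(tree)) {
    if (is.null(time_point)) time_point <- root_age(tree) / 2
    part <- sibling_tips(tree, time_point)
  }
  rows <- lapply(fractions, function(f) {
    m <- floor(f * nrow(pts))
    if (m < 3L) {
      warning("fraction ", f, " yields fewer than 3 points; skipped")
      return(data.frame(fraction = f, n = m, mean_p = NA_real_, se_p = NA_real_))
    }
    ps <- vapply(seq_len(n_repeats), function(r) {
      idx <- if (m == nrow(pts)) seq_len(nrow(pts)) else sample.int(nrow(pts), m)
      sub <- pts[idx, , drop = FALSE]
      if (is.null(part))
        triangularity_test(sub, n_shuffles = n_shuffles)$p_value
      else
        suppressWarnings(
          triangularity_test(sub, n_shuffles = n_shuffles, scheme = "sibswap",
                             partition = part)$p_value)
    }, numeric(1))
    data.frame(fraction = f, n = m, mean_p = mean(ps),
               se_p = stats::sd(ps) / sqrt(n_repeats))
  })
  do.call(rbind, rows)
}
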