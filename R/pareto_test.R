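# The t-ratio statistic and its permutation test of triangularity.

#' The t-ratio: fitted triangle area over convex hull area
#'
#' The t-ratio is the area of the minimal-area enclosing triangle divided
#' by the area of the data's convex hull.  For data that fill a triangle
#' the hull nearly coincides with the fitted triangle and the ratio is
#' close to 1; for structureless clouds the corners of any enclosing
#' triangle stay empty and the ratio is markedly larger than 1.  In hard
#' enclosure mode the ratio is always >= 1.
#'
#' @param points A point cloud.
#' @param soft_fraction Passed to [fit_enclosing_triangle()].
#' @return A single number >= 1 (hard mode).
#' @export
t_ratio <- function(points, soft_fraction = 0) {
  pts <- as_point_cloud(points)
  tri <- fit_enclosing_triangle(pts, soft_fraction = soft_fraction)
  tri$area / convex_hull_area(pts)
}

#' Independently shuffle the two trait columns
#'
#' Permutes the x column and, independently, the y column of a point cloud,
#' destroying their joint structure while preserving both marginal
#' multisets.
#'
#' @param points A point cloud.
#' @param seed Optional integer seed.
#' @return A point cloud of the same dimensions.
#' @export
shuffle_independent <- function(points, seed = NULL) {
  pts <- as_point_cloud(points)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pts)
  out <- cbind(pts[sample.int(n), 1], pts[sample.int(n), 2])
  dimnames(out) <- dimnames(pts)
  out
}

# shuffle x and y independently within each group of a factor/partition
.shuffle_within <- function(pts, group) {
  out <- pts
  for (g in split(seq_len(nrow(pts)), group)) {
    if (length(g) > 1L) {
      out[g, 1] <- pts[g[sample.int(length(g))], 1]
      out[g, 2] <- pts[g[sample.int(length(g))], 2]
    }
  }
  out
}

#' Permutation test of triangularity (t-ratio test)
#'
#' Compares the observed t-ratio against t-ratios of shuffled datasets.
#' The p-value is the proportion of shuffled datasets whose t-ratio is
#' lower than the observed one; triangularity is conventionally called
#' significant at p < 0.05.
#'
#' @param points A point cloud.
#' @param n_shuffles Number of shuffled datasets (default 1000, giving a
#'   p resolution of 0.001).
#' @param scheme Shuffle scheme: `"independent"` permutes each trait across
#'   all points; `"sibswap"` permutes within the groups of `partition`
#'   (sibling tips of a time-calibrated tree, see [sibling_tips()]);
#'   `"within_class"` permutes within the levels of `classes`.
#' @param partition A `sibling_partition` (required for `"sibswap"`).
#' @param classes Factor of class labels aligned to rows (required for
#'   `"within_class"`).
#' @param seed Optional integer seed.
#' @param conservative_p If `TRUE`, report the add-one estimator
#'   `(1 + #lower) / (1 + n_shuffles)` instead of the plain proportion.
#' @param soft_fraction Passed to [t_ratio()].
#' @return An object of class `tratio_result` with fields
#'   `t_ratio_observed`, `t_ratio_null`, `p_value`, `n_shuffles`,
#'   `shuffle_scheme`, `seed` and `redrawn` (degenerate shuffles redrawn).
#' @export
triangularity_test <- function(points, n_shuffles = 1000,
                               scheme = c("independent", "sibswap", "within_class"),
                               partition = NULL, classes = NULL, seed = NULL,
                               conservative_p = FALSE, soft_fraction = 0) {
  scheme <- match.arg(scheme)
  pts <- as_point_cloud(points)
  if (!is.null(seed)) set.seed(seed)
  group <- switch(scheme,
    independent = NULL,
    sibswap = {
      if (is.null(partition)) stop("scheme 'sibswap' requires a partition")
      partition_groups(partition, rownames(pts))
    },
    within_class = {
      if (is.null(classes)) stop("scheme 'within_class' requires classes")
      if (length(classes) != nrow(pts)) stop("classes must align with rows")
      as.factor(classes)
    })
  observed <- t_ratio(pts, soft_fraction = soft_fraction)
  null <- numeric(n_shuffles)
  redrawn <- 0L
  for (i in seq_len(n_shuffles)) {
    val <- NA_real_
    for (try in 1:100) {
      shuf <- if (is.null(group)) shuffle_independent(pts) else .shuffle_within(pts, group)
      val <- tryCatch(t_ratio(shuf, soft_fraction = soft_fraction),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      redrawn <- redrawn + 1L
    }
    if (!is.finite(val)) stop("shuffle ", i, ": repeated degenerate geometry")
    null[i] <- val
  }
  if (redrawn > 0) message(redrawn, " degenerate shuffles redrawn")
  p <- if (conservative_p) (1 + sum(null < observed)) / (1 + n_shuffles)
       else sum(null < observed) / n_shuffles
  structure(list(t_ratio_observed = observed, t_ratio_null = null,
                 p_value = p, n_shuffles = as.integer(n_shuffles),
                 shuffle_scheme = scheme, seed = seed, redrawn = redrawn),
            class = "tratio_result")
}

#' @export
print.tratio_result <- function(x, ...) {
  cat("t-ratio permutation test of triangularity\n")
  cat(sprintf("  observed t-ratio : %.4f\n", x$t_ratio_observed))
  cat(sprintf("  null mean t-ratio: %.4f (%d %s shuffles)\n",
              mean(x$t_ratio_null), x$n_shuffles, x$shuffle_scheme))
  cat(sprintf("  p-value          : %.4g%s\n", x$p_value,
              if (x$p_value < 0.05) "  (significant triangularity)" else ""))
  invisible(x)
}
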