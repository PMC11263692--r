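# Archetype feature enrichment: distance binning, density profiles, and
# nearest-bin significance tests.

#' Euclidean distances from a vertex in the trait plane
#'
#' @param points A point cloud.
#' @param vertex A length-2 numeric vector (a triangle vertex).
#' @return Numeric vector of distances, one per row.
#' @export
distances_to_vertex <- function(points, vertex) {
  pts <- as_point_cloud(points)
  vertex <- as.numeric(vertex)
  if (length(vertex) != 2L || !all(is.finite(vertex)))
    stop("vertex must be a finite 2-D point")
  sqrt((pts[, 1] - vertex[1])^2 + (pts[, 2] - vertex[2])^2)
}

#' Assign species to equally populated distance bins
#'
#' Sorts species by distance (ties broken by stable input order) and cuts
#' them into `n_bins` contiguous groups whose sizes differ by at most 1;
#' when the count does not divide evenly, the extra species go to the bins
#' nearest the vertex.
#'
#' @param distances Numeric vector of distances from the vertex.
#' @param n_bins Number of bins (default 8).
#' @return Integer vector of bin indices (1 = nearest the vertex).
#' @export
equal_population_bins <- function(distances, n_bins = 8) {
  n <- length(distances)
  if (n < n_bins)
    stop("only ", n, " species with the feature; use n_bins <= ", n)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  ord <- order(distances)            # stable: ties keep input order
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  bin
}

#' Density profile of a feature over distance bins
#'
#' @param values Feature values aligned to the binned species.
#' @param bins Bin assignment from [equal_population_bins()].
#' @return A data frame with per-bin `mean`, `se` (sample SD / sqrt(n))
#'   and `n`, ordered by increasing distance from the vertex.
#' @export
density_profile <- function(values, bins) {
  stopifnot(length(values) == length(bins))
  by_bin <- split(values, bins)
  data.frame(bin = as.integer(names(by_bin)),
             mean = vapply(by_bin, mean, numeric(1)),
             se = vapply(by_bin, function(v)
               if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               numeric(1)),
             n = lengths(by_bin), row.names = NULL)
}

#' Nearest-bin enrichment test
#'
#' Two-sample t-test (Welch by default) between the feature values in the
#' bin nearest the vertex and the values of all remaining species.  The
#' feature is called maximized at the vertex if the nearest-bin mean is
#' higher and p < alpha, minimized if lower and p < alpha, none otherwise.
#'
#' @param values Feature values aligned to `bins`.
#' @param bins Bin assignment from [equal_population_bins()].
#' @param alpha Significance level for the direction call (default 0.05).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A list with `p_value`, `direction`
#'   (`"maximized"`/`"minimized"`/`"none"`), `t_statistic`,
#'   `mean_nearest`, `mean_rest`.
#' @export
enrichment_test <- function(values, bins, alpha = 0.05, pooled = FALSE) {
  near <- values[bins == 1L]
  rest <- values[bins != 1L]
  if (length(near) < 2L || length(rest) < 2L)
    stop("nearest bin and remainder each need at least 2 feature values")
  if (stats::var(near) == 0 && stats::var(rest) == 0) {
    warning("zero variance in both groups; t statistic undefined, p set to 1")
    return(list(p_value = 1, direction = "none", t_statistic = 0,
                mean_nearest = mean(near), mean_rest = mean(rest)))
  }
  tt <- stats::t.test(near, rest, var.equal = pooled)
  direction <- if (tt$p.value < alpha) {
    if (mean(near) > mean(rest)) "maximized" else "minimized"
  } else "none"
  list(p_value = tt$p.value, direction = direction,
       t_statistic = unname(tt$statistic),
       mean_nearest = mean(near), mean_rest = mean(rest))
}

#' Feature enrichment profiles at every vertex
#'
#' For each (vertex, feature) pair: species missing the feature are
#' excluded, the remaining species are binned by Euclidean distance from
#' the vertex into equally populated bins (so bin sizes differ across
#' features), and the per-bin density profile and nearest-bin test are
#' computed.  No multiple-testing correction is applied by default; with
#' `bonferroni = TRUE` the p-values are multiplied by the number of
#' (vertex, feature) pairs.
#'
#' @param table An analysis-ready trait table (see
#'   [preprocess_trait_table()]).
#' @param polytope A fitted `polytope` (labelled vertices).
#' @param features Numeric columns of `table` to profile (default
#'   `rel_testes_mass`, `clutch_z`, `genome_size`).
#' @param n_bins Number of equally populated bins (default 8).
#' @param alpha Significance level for direction calls.
#' @param bonferroni Apply a Bonferroni correction over all profiles.
#' @return A list of class `enrichment_profiles`; each element has
#'   `vertex`, `feature`, `profile` (data frame), `p_value`, `direction`,
#'   `n_species` and `bin_membership` (species per bin).
#' @export
enrich_all <- function(table, polytope, features = c("rel_testes_mass",
                                                     "clutch_z", "genome_size"),
                       n_bins = 8, alpha = 0.05, bonferroni = FALSE) {
  if (is.data.frame(table) && !"log10_body_mass" %in% names(table))
    table <- log10_traits(table)
  pts <- as_point_cloud(table)
  verts <- polytope$vertices
  out <- list()
  for (feat in features) {
    if (!feat %in% names(table)) stop("feature not in table: ", feat)
    if (!any(is.finite(table[[feat]]))) {
      warning("feature '", feat, "': all values missing, skipped")
      features <- setdiff(features, feat)
    }
  }
  n_tests <- nrow(verts) * length(features)
  for (vi in seq_len(nrow(verts))) {
    vname <- rownames(verts)[vi]
    if (is.null(vname)) vname <- paste0("V", vi)
    for (feat in features) {
      vals <- table[[feat]]
      has <- is.finite(vals)
      d <- distances_to_vertex(pts[has, , drop = FALSE], verts[vi, ])
      bins <- equal_population_bins(d, n_bins)
      test <- enrichment_test(vals[has], bins, alpha = alpha)
      p <- test$p_value
      if (bonferroni) {
        p <- min(1, p * n_tests)
        if (p >= alpha && test$direction != "none") test$direction <- "none"
      }
      memb <- split(table$species[has], bins)
      out[[paste(vname, feat, sep = ".")]] <-
        list(vertex = vname, feature = feat,
             profile = density_profile(vals[has], bins),
             p_value = p, direction = test$direction,
             t_statistic = test$t_statistic,
             n_species = sum(has), bin_membership = memb)
    }
  }
  structure(out, class = "enrichment_profiles", bonferroni = bonferroni)
}

#' Summary table of enrichment profiles
#'
#' @param object An `enrichment_profiles` list.
#' @param ... Unused.
#' @return A data frame with one row per (vertex, feature) profile.
#' @export
summary.enrichment_profiles <- function(object, ...) {
  do.call(rbind, lapply(object, function(e)
    data.frame(vertex = e$vertex, feature = e$feature, n = e$n_species,
               p_value = e$p_value, direction = e$direction,
               row.names = NULL)))
}

#' @export
print.enrichment_profiles <- function(x, ...) {
  cat("Archetype feature enrichment\n")
  print(summary(x))
  invisible(x)
}
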