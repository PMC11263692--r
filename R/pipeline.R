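# Orchestration of the full analysis: preprocess -> fit/select ->
# triangularity tests (full + subgroups) -> enrichment -> phylogenetic
# robustness -> subsampling robustness.

.tratio_summary <- function(x) {
  list(t_ratio_observed = x$t_ratio_observed,
       t_ratio_null_mean = mean(x$t_ratio_null),
       p_value = x$p_value, n_shuffles = x$n_shuffles,
       shuffle_scheme = x$shuffle_scheme)
}

#' Run the full Pareto front analysis
#'
#' Executes every stage of the pipeline on a trait table (and optionally a
#' time-calibrated tree): preprocessing, archetype-number selection,
#' triangle fitting with bootstrap vertex uncertainty, triangularity tests
#' for the full set and the standard subgroups (thermoregulation and
#' fertilization modes, each class), feature enrichment at the vertices,
#' the SibSwap robustness curve, and class-balanced plus fractional
#' subsampling checks.  Stage failures are recorded in the report and do
#' not abort independent stages; phylogenetic stages are skipped with a
#' note when no tree is given.
#'
#' @param traits A trait table (from [read_trait_table()] or
#'   [synthetic_trait_table()]) or a path to one.
#' @param tree Optional `ape::phylo` tree or path to a Newick file.
#' @param config Named list overriding defaults: `n_shuffles` (1000),
#'   `n_bins` (8), `ks` (2:5), `bootstrap_B` (200), `features`,
#'   `time_points` (NULL = automatic grid), `phylo_n_repeats` (100),
#'   `phylo_n_shuffles` (100), `fractions` (0.05..0.8),
#'   `fraction_n_repeats` (30), `min_subgroup_n` (50).
#' @param seed Integer seed governing every random stage.
#' @return A list of class `pareto_report`.
#' @export
run_full_analysis <- function(traits, tree = NULL, config = list(), seed = 1L) {
  cfg <- list(n_shuffles = 1000L, n_bins = 8L, ks = 2:5, bootstrap_B = 200L,
              features = c("rel_testes_mass", "clutch_z", "genome_size"),
              time_points = NULL, phylo_n_repeats = 100L,
              phylo_n_shuffles = 100L, fractions = seq(0.1, 0.8, by = 0.1),
              fraction_n_repeats = 30L, min_subgroup_n = 50L)
  cfg[names(config)] <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (!"log10_body_mass" %in% names(traits))
    traits <- preprocess_trait_table(traits)
  if (is.character(tree)) tree <- read_timetree(tree, species = traits$species)
  set.seed(seed)
  pts <- as_point_cloud(traits)
  report <- list(seed = seed, config = cfg, n_species = nrow(pts),
                 class_counts = as.list(table(traits$taxon_class)))

  report$model_selection <- stage("select_k", {
    sel <- select_k(pts, ks = cfg$ks)
    sel[c("ks", "sse", "improvement", "selected_k")]
  })
  report$triangle <- stage("fit", {
    tri <- fit_enclosing_triangle(pts)
    boot <- bootstrap_vertices(pts, B = cfg$bootstrap_B, reference = tri)
    list(vertices = tri$vertices, area = tri$area,
         hull_area = convex_hull_area(pts),
         vertex_sd = boot$vertex_sd, bootstrap_B = cfg$bootstrap_B)
  })
  report$triangularity <- stage("triangularity", {
    .tratio_summary(triangularity_test(pts, n_shuffles = cfg$n_shuffles))
  })

  report$subgroups <- stage("subgroups", {
    specs <- list(c("thermoregulation", "endotherm"),
                  c("thermoregulation", "ectotherm"),
                  c("fertilization", "internal"),
                  c("fertilization", "external"))
    for (cl in unique(traits$taxon_class)) specs <- c(specs, list(c("class", cl)))
    out <- list()
    for (s in specs) {
      sub <- tryCatch(subgroup(traits, s[1], s[2]), error = function(e) NULL)
      key <- paste(s[1], s[2], sep = ".")
      if (is.null(sub) || nrow(sub) < cfg$min_subgroup_n) {
        out[[key]] <- list(skipped = TRUE, n = if (is.null(sub)) 0L else nrow(sub))
      } else {
        res <- triangularity_test(as_point_cloud(sub), n_shuffles = cfg$n_shuffles)
        out[[key]] <- c(list(n = nrow(sub)), .tratio_summary(res))
      }
    }
    out
  })

  report$enrichment <- stage("enrichment", {
    feats <- intersect(cfg$features, names(traits))
    feats <- feats[vapply(feats, function(f) any(is.finite(traits[[f]])), logical(1))]
    if (!length(feats)) list(skipped = TRUE, reason = "no usable features")
    else {
      tri <- fit_enclosing_triangle(pts)
      prof <- enrich_all(traits, tri, features = feats, n_bins = cfg$n_bins)
      summary(prof)
    }
  })

  if (is.null(tree)) {
    report$phylo <- list(skipped = TRUE, reason = "no tree supplied")
    report$fraction_subsampling <- list(skipped = TRUE, reason = "no tree supplied")
  } else {
    report$phylo <- stage("sibswap_curve", {
      keep <- rownames(pts) %in% tree$tip.label
      if (sum(keep) < nrow(pts))
        message(nrow(pts) - sum(keep), " species not in the tree excluded from phylo stages")
      as.data.frame(sibswap_curve(pts[keep, , drop = FALSE], tree,
                                  time_points = cfg$time_points,
                                  n_shuffles = cfg$phylo_n_shuffles,
                                  n_repeats = cfg$phylo_n_repeats))
    })
    report$fraction_subsampling <- stage("fraction_subsampling", {
      keep <- rownames(pts) %in% tree$tip.label
      fraction_subsample_curve(pts[keep, , drop = FALSE], tree,
                               fractions = cfg$fractions,
                               n_repeats = cfg$fraction_n_repeats,
                               n_shuffles = cfg$phylo_n_shuffles)
    })
  }

  report$class_balanced <- stage("class_balanced", {
    counts <- table(traits$taxon_class)
    n_per <- min(counts)
    if (length(counts) < 2L || n_per < 3L) list(skipped = TRUE)
    else c(list(n_per_class = as.integer(n_per),
                n_total = as.integer(n_per * length(counts))),
           .tratio_summary(class_balanced_subsample_test(
             pts, traits$taxon_class, n_per, n_shuffles = cfg$n_shuffles)))
  })

  class(report) <- "pareto_report"
  report
}

#' @export
print.pareto_report <- function(x, ...) {
  cat("Pareto front analysis report\n")
  cat(sprintf("  species: %d  seed: %d\n", x$n_species, x$seed))
  if (!is.null(x$model_selection$selected_k))
    cat(sprintf("  selected number of archetypes: %d\n", x$model_selection$selected_k))
  if (!is.null(x$triangularity$t_ratio_observed))
    cat(sprintf("  t-ratio %.3f, p = %.4g (%d shuffles)\n",
                x$triangularity$t_ratio_observed, x$triangularity$p_value,
                x$triangularity$n_shuffles))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report A `pareto_report` (or any list of results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
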