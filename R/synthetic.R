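# Generators for synthetic trait tables, clouds, features and trees with
# the statistical structure the analysis assumes.

#' Default generating triangle in log10 trait units
#'
#' Vertices roughly matching the occupancy of the tetrapod sperm length vs
#' body mass plane: T1 small-bodied short-sperm, T2 intermediate-bodied
#' long-sperm, T3 large-bodied intermediate-sperm.  Units are log10 grams
#' (x) and log10 micrometres (y).
#'
#' @return A 3 x 2 matrix.
#' @export
default_triangle <- function() {
  m <- rbind(T1 = c(0.5, 1.2), T2 = c(3.0, 3.4), T3 = c(8.0, 1.9))
  colnames(m) <- c("x", "y")
  m
}

#' Sample points uniformly inside a triangle
#'
#' Barycentric sampling: two independent uniforms, reflected into the unit
#' simplex, map each draw uniformly into the triangle; optional isotropic
#' Gaussian jitter is added afterwards.  Class labels are assigned by
#' mixture weights.
#'
#' @param n_species Number of points.
#' @param vertices 3 x 2 matrix of triangle vertices.
#' @param noise_sd SD of Gaussian jitter added to both coordinates
#'   (default 0).
#' @param class_labels Labels for the class mixture.
#' @param class_weights Mixture weights (sum to 1).
#' @param seed Optional integer seed.
#' @return A point cloud with row names `sp1..spn`; attribute `classes`
#'   holds the class labels.
#' @export
gen_triangle_cloud <- function(n_species, vertices = default_triangle(),
                               noise_sd = 0,
                               class_labels = c("Amphibia", "Aves", "Mammalia", "Reptilia"),
                               class_weights = c(231, 399, 643, 115) / 1388,
                               seed = NULL) {
  vertices <- as_point_cloud(vertices)
  if (nrow(vertices) != 3L || shoelace_area(vertices) <= 0)
    stop("vertices must form a non-degenerate triangle")
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n_species); v <- stats::runif(n_species)
  refl <- u + v > 1
  u[refl] <- 1 - u[refl]; v[refl] <- 1 - v[refl]
  A <- vertices[1, ]; B <- vertices[2, ]; C <- vertices[3, ]
  pts <- cbind(A[1] + u * (B[1] - A[1]) + v * (C[1] - A[1]),
               A[2] + u * (B[2] - A[2]) + v * (C[2] - A[2]))
  if (noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(2 * n_species, sd = noise_sd), ncol = 2)
  rownames(pts) <- paste0("sp", seq_len(n_species))
  colnames(pts) <- c("x", "y")
  attr(pts, "classes") <- sample(class_labels, n_species, replace = TRUE,
                                 prob = class_weights)
  pts
}

#' Sample a structureless cloud (null model)
#'
#' Isotropic Gaussian or uniform-rectangle cloud, the null geometry against
#' which triangularity should not be detected systematically.
#'
#' @param n_species Number of points.
#' @param center Cloud centre (length 2).
#' @param sd Isotropic SD (Gaussian) or half-width (uniform).
#' @param shape `"gaussian"` or `"uniform"`.
#' @param seed Optional integer seed.
#' @return A point cloud with row names.
#' @export
gen_cloud <- function(n_species, center = c(0, 0), sd = 1,
                      shape = c("gaussian", "uniform"), seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  pts <- switch(shape,
    gaussian = matrix(stats::rnorm(2 * n_species, sd = sd), ncol = 2),
    uniform = matrix(stats::runif(2 * n_species, -sd, sd), ncol = 2))
  pts <- sweep(pts, 2, center, "+")
  rownames(pts) <- paste0("sp", seq_len(n_species))
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate a feature enriched at a vertex
#'
#' Expected value decays exponentially with Euclidean distance from the
#' vertex: `baseline + amplitude * exp(-d / decay) + noise`.
#'
#' @param points A point cloud.
#' @param vertex The enriched vertex (length 2).
#' @param amplitude Decay amplitude (0 = feature independent of position).
#' @param decay Decay length in trait-plane units.
#' @param noise_sd SD of additive Gaussian noise.
#' @param baseline Constant offset.
#' @param seed Optional integer seed.
#' @return Numeric feature vector aligned to rows.
#' @export
gen_enriched_feature <- function(points, vertex, amplitude = 1, decay = 1,
                                 noise_sd = 0, baseline = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- distances_to_vertex(points, vertex)
  baseline + amplitude * exp(-d / decay) +
    if (noise_sd > 0) stats::rnorm(length(d), sd = noise_sd) else 0
}

#' Generate an ultrametric pure-birth (Yule) tree
#'
#' @param n_leaves Number of leaves.
#' @param birth_rate Speciation rate (> 0); smaller rates give older roots.
#' @param seed Optional integer seed.
#' @return An `ape::phylo` ultrametric tree, leaves `sp1..spn` at age 0.
#' @export
gen_yule_tree <- function(n_leaves, birth_rate = 0.1, seed = NULL) {
  if (birth_rate <= 0) stop("birth rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("sp", seq_len(n_leaves))
  tree
}

#' Evolve two independent Brownian traits along a tree
#'
#' Standard Brownian motion on branches: trait change on a branch is
#' Gaussian with variance `bm_sigma^2 * branch length`, so two leaves
#' covary in proportion to their shared path length from the root.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param bm_sigma Brownian rate (SD per unit sqrt(time), >= 0).
#' @param root Ancestral state (length 2).
#' @param seed Optional integer seed.
#' @return A point cloud with the tree's leaf names as row names.
#' @export
gen_brownian_traits <- function(tree, bm_sigma = 1, root = c(0, 0), seed = NULL) {
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- ape::rTraitCont(tree, model = "BM", sigma = bm_sigma, ancestor = FALSE,
                       root.value = root[1])
  y <- ape::rTraitCont(tree, model = "BM", sigma = bm_sigma, ancestor = FALSE,
                       root.value = root[2])
  pts <- cbind(x = unname(x), y = unname(y))
  rownames(pts) <- tree$tip.label
  pts
}

#' Build a synthetic trait table around a point cloud
#'
#' Wraps a point cloud (log10 body mass, log10 sperm length) into the
#' trait-table layout, back-transforming the raw traits and optionally
#' attaching planted secondary features.
#'
#' @param points A point cloud (log10 units).
#' @param classes Class labels aligned to rows; defaults to the cloud's
#'   `classes` attribute or `"SimClass"`.
#' @param features Optional named list of numeric feature vectors (e.g.
#'   `clutch_size`, `testes_mass`, `genome_size`) aligned to rows.
#' @return A `trait_table` data frame.
#' @export
synthetic_trait_table <- function(points, classes = NULL, features = list()) {
  pts <- as_point_cloud(points)
  if (is.null(rownames(pts))) rownames(pts) <- paste0("sp", seq_len(nrow(pts)))
  if (is.null(classes)) classes <- attr(points, "classes")
  if (is.null(classes)) classes <- rep("SimClass", nrow(pts))
  tab <- data.frame(species = rownames(pts), taxon_class = classes,
                    body_mass = 10^pts[, 1], sperm_length = 10^pts[, 2],
                    clutch_size = NA_real_, testes_mass = NA_real_,
                    genome_size = NA_real_, stringsAsFactors = FALSE)
  for (nm in names(features)) tab[[nm]] <- features[[nm]]
  rownames(tab) <- NULL
  structure(tab, n_dropped = 0L, class = c("trait_table", "data.frame"))
}
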