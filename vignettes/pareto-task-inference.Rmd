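---
title: "Pareto front inference in trait space: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto front inference in trait space: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretofit)
```

## The model

Pareto task inference treats a species' phenotype as a compromise between
several tasks it cannot optimise simultaneously. If fitness is an increasing
function of k task performances, each maximised at its own *archetype*
phenotype and decaying with distance from it, evolutionarily stable
phenotypes fill the convex hull of the archetypes: a line segment for two
tasks, a triangle for three, and so on. The signature of a three-way
trade-off in a two-dimensional trait space is therefore a *triangular*
occupancy pattern whose vertices host the archetypal species.

`paretofit` applies this logic to cross-species data, with the motivating
application being sperm length (µm) against body mass (g) in tetrapods, both
log10-transformed before analysis. The package does not compute performance
functions or fitness weights themselves — only the geometry of occupancy,
its statistical support, and the secondary traits enriched near each vertex.

## Fitting: how many archetypes, and where

Two complementary fits are used, mirroring standard practice in this
literature:

* **PCHA (principal convex hull / archetypal analysis)**, `fit_pcha()`,
  approximates every point as a convex combination of k archetypes that are
  themselves convex combinations of the data, minimising reconstruction SSE.
  It is used for *model selection*: `select_k()` compares k = 2..5.
* **The exact minimal-area enclosing triangle**, `fit_enclosing_triangle()`,
  places the three vertices once a triangle is chosen. The original
  literature uses a minimum-volume simplex fit with soft constraints
  (a hyperspectral-unmixing algorithm); we instead solve the hard-enclosure
  problem exactly, which is deterministic, has no free regularisation
  parameter, and can be verified against a brute-force oracle. The practical
  consequence is that the t-ratio (below) is always ≥ 1. A `soft_fraction`
  option trims the most extreme points before fitting for users who want
  outlier tolerance; it is off by default because the reference analyses
  behave like hard enclosure (observed t-ratios just above 1).

The exact triangle solver exploits the classical optimality structure of the
minimal enclosing triangle: at least one side is flush with a hull edge and
every non-flush side touches the hull at the side's midpoint. Enumerating
flush-edge triples and flush-pair-plus-bisected-vertex configurations (the
one-flush/two-midpoint family is a constant-area family whose boundary
members are of the latter type) yields the exact optimum; candidates are
validated by containment. The enumeration is O(h³–h⁴) in the hull size h,
implemented in C++; since h grows only logarithmically with n this is
microseconds to milliseconds per fit.

### PCHA implementation notes

The weights of points on archetypes are solved *exactly* per iteration by
enumerating support subsets of the k-simplex (k ≤ 5 here, so at most 31
subsets, each a small equality-constrained least-squares solve vectorised
over all points). Archetype weights are updated by projected gradient with
backtracking, so the SSE is monotone non-increasing within a fit.
Initialisation is a deterministic furthest-sum selection, which makes fits
reproducible without a seed. With k = 1 the archetype is the point mean and
the SSE the total sum of squares — this is the baseline for model selection.
The relaxation parameter `delta` (archetypes allowed slightly outside the
hull) defaults to 0.

### The elbow rule

SSE is monotone non-increasing in k, so "the best k" must be an elbow
criterion. `select_k()` computes the relative improvement
(SSE(k−1) − SSE(k)) / SSE(k−1) and selects the largest k whose improvement
exceeds `threshold` (default 0.2). One guard is added: improvements are
ignored once the previous model already explains more than 99% of the total
variance (`sse_floor = 0.01`). The guard matters because for noise-free
triangular fills SSE(3) is essentially zero, and the *ratio* between two
near-zero SSEs at k = 4, 5 is numerically meaningless; without the floor the
rule would chase noise. With it, uniform triangle fills select k = 3 and
noisy one-dimensional segments select k = 2 (provided the perpendicular
noise accounts for under ~1% of total variance — wider bands are genuinely
two-dimensional and the rule will, correctly, say so).

### Vertex labels and uncertainty

Vertices are returned counter-clockwise and labelled by an anchor rule:
T2 = highest y (longest sperm), T3 = highest x among the rest (largest body
mass), T1 = the remainder. `bootstrap_vertices()` resamples species with
replacement, refits, matches vertices to the reference fit by the
minimum-total-distance permutation, and reports per-vertex covariances.
Degenerate resamples (collinear hulls) are redrawn and counted.

## The t-ratio test

The *t-ratio* is the fitted-triangle area divided by the convex hull area.
Triangle-filling data give values near 1; structureless clouds leave the
corners of any enclosing triangle empty and give values well above 1. The
permutation test (`triangularity_test()`) compares the observed t-ratio with
t-ratios of shuffled datasets; the p-value is the *plain proportion of null
t-ratios strictly lower than the observed one* — matching the convention of
the reference analyses — with an optional add-one estimator
(`conservative_p = TRUE`) for users who prefer never reporting exactly 0.
The default 1000 shuffles give a p resolution of 0.001. Degenerate shuffles
are redrawn, not dropped, so the null size is exact.

Three shuffle schemes are provided:

* `independent` — each trait permuted across all species (marginals
  preserved, joint structure destroyed);
* `sibswap` — each trait permuted independently *within* sibling-tip groups
  of a time-calibrated tree, preserving both the marginals and the
  phylogenetic block structure;
* `within_class` — SibSwap with taxonomic classes as the groups.

### Sibling tips and the robustness curve

`sibling_tips()` cuts every branch spanning a chosen age t (leaves at age 0,
ages increasing toward the root; non-ultrametric trees are accepted with a
warning and leaf ages forced to 0). Each cut lineage's descendant leaves form
one group; a node whose age equals t exactly heads its own group (the cut is
closed at the node — a deterministic tie-break). Partitions at smaller t
refine partitions at larger t, which the tests assert on random trees.
Multifurcations need no special handling: every child branch crossing the
time slice simply yields its own group.

`sibswap_curve()` repeats the SibSwap test across a time grid and flags,
scanning from the oldest time point toward the present, where the mean
p-value significantly exceeds 0.05 (one-sample one-sided t-test), i.e. where
phylogenetic dependence starts to erode the signal. One behaviour deserves
emphasis: **as t approaches the present the groups approach singletons and
the shuffles lose their degrees of freedom** — shuffled clouds tie with the
observed one and the strict-proportion p collapses toward 0. This is a
property of the statistic's definition, not evidence of triangularity; the
curve therefore also reports the number of groups, and conclusions should be
drawn only where groups retain permutation support. The tip-averaging
variant (`modified_sibswap_points()` / `modified_sibswap_test()`) is the
designed remedy for recent time points: both traits are averaged within each
sibling-tip group and the averaged points are tested with independent
shuffles, as independent data points.

### Sampling robustness

`class_balanced_subsample_test()` draws the same number of species per class
(typically the smallest class size) and uses within-class shuffles as nulls,
so numerically dominant classes cannot carry the signal by themselves.
`fraction_subsample_curve()` repeats the test on random fractions of the
species (default 30 repeats per fraction, reporting mean ± SE of p). When a
tree is supplied, nulls are SibSwap at a configurable `time_point`; the
reference analyses do not state the time point used per subsample, so the
default — half the root age — is an explicit package choice, exposed as an
argument.

## Feature enrichment at the vertices

For each vertex and each secondary feature (by default the within-class
log-log regression residual of testes mass, the within-class z-score of
clutch size, and genome size), species carrying the feature are sorted by
Euclidean distance from the vertex in the log-log plane and split into 8
equally populated bins (sizes differing by at most 1, the remainder going to
the bins nearest the vertex; ties in distance broken by stable input order).
Binning is *per feature*, not global — species missing a feature are
excluded before binning, which is why bin sizes differ across features. The
enrichment call compares the nearest bin against all remaining species with
a two-sided Welch t-test (pooled variance optional); a feature is "maximized"
at a vertex if the nearest-bin mean is higher with p below alpha, "minimized"
if lower. No multiple-testing correction is applied by default, matching how
such profiles are conventionally reported; a Bonferroni option over all
(vertex, feature) pairs is available.

## Preprocessing conventions

`read_trait_table()` accepts CSV/TSV with a header and a column map so
arbitrary deposits bind without code edits; `""`, `NA`, `NaN`, `N/A` all
parse as missing. Rows lacking (or with non-positive) body mass or sperm
length are dropped with a logged count; duplicate species names are an error
rather than averaged, because comparative tables should carry one value per
species. Relative testes mass is the residual of an ordinary (not
phylogenetic) least-squares fit of log10 testes mass on log10 body mass
within each class; classes with fewer than 3 records, or no body-mass
variation, get missing residuals with a warning rather than an error so
subgroup runs never fail. Clutch z-scores are within-class with the sample
SD. Subgroups: endotherm = Aves + Mammalia, internal fertilizer = Aves +
Mammalia + Reptilia, external = Amphibia, overridable per species through
optional `thermoregulation` / `fertilization` columns.

## What the synthetic generators do and do not emulate

The generators make every stage testable without downloads:

* `gen_triangle_cloud()` — uniform barycentric sampling inside a triangle
  whose default vertices, (0.5, 1.2), (3.0, 3.4), (8.0, 1.9) in log10
  (grams, micrometres), mimic the aspect of the tetrapod trait plane: small
  amphibian-like species with short sperm, intermediate-bodied species with
  long sperm, very large species with intermediate sperm. Class labels
  follow the empirical mixture 231:399:643:115 across
  Amphibia/Aves/Mammalia/Reptilia. Optional Gaussian jitter.
* `gen_cloud()` — isotropic Gaussian or uniform rectangle, the null
  geometry.
* `gen_enriched_feature()` — baseline + amplitude · exp(−distance/decay) +
  Gaussian noise, the monotone density profile enrichment assumes.
* `gen_yule_tree()` / `gen_brownian_traits()` — ultrametric pure-birth trees
  and two independent Brownian traits, supplying realistic phylogenetic
  autocorrelation (leaf covariance = shared path length × rate²).

Real comparative data differ in ways these generators deliberately ignore:
occupancy inside the triangle is not uniform (classes cluster), measurement
error is heteroskedastic across sources, secondary features are mutually
correlated, and real trees are neither pure-birth nor perfectly calibrated.
Passing tests therefore demonstrate that the *machinery* is correct and
calibrated under its stated assumptions — not that any particular empirical
dataset is triangular.

## Numerical choices

* Containment and degeneracy tolerances in the triangle solver scale with
  the squared hull diameter (10⁻⁹ relative); collinear inputs raise a
  degenerate-geometry error rather than returning nonsense.
* PCHA stops when the relative SSE change falls below 10⁻¹⁰ of the total SS
  or after 300 outer iterations.
* The p-value uses a strict inequality (ties count against rejection),
  exactly as defined in the source convention.
* Node-age ties at a time slice are closed at the node (see above).
* All randomised functions accept a `seed`; given one, results are
  bit-reproducible. `run_full_analysis()` seeds once and runs stages in a
  fixed order.

## Problem sizes used by the checks

The test suite exercises the pipeline at the scales it is designed for while
staying desk-sized: the calibration study uses 100 triangular and 100
Gaussian datasets of 1000 points with 500 shuffles each; vertex recovery
uses 2000 noise-free points; enrichment power uses 100 runs of 800 species
at amplitude twice the noise SD plus 500 flat-feature runs; oracle
equivalence uses 50 point sets of 10–50 points. The acceptance script runs
the full pipeline once at the 1388-species study scale. These sizes are the
package's choices for a thorough-but-quick check; all of them can be scaled
up through function arguments.

## Known limitations

* Only 2-D trait spaces: the minimal enclosing simplex is implemented for
  triangles, matching the motivating analysis. Higher-dimensional polytope
  fitting is out of scope.
* The hard-enclosure triangle is sensitive to extreme outliers (a single
  stray point enlarges the triangle); use `soft_fraction` or inspect hulls
  when applying it to raw compilations.
* The strict-proportion p-value degenerates when permutation support
  vanishes (near-singleton SibSwap partitions; see above).
* Enrichment tests treat species as independent; phylogenetic
  non-independence of the *features* is not corrected — only the
  triangularity test has phylogeny-aware nulls, as in the source analyses.
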