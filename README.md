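# paretofit

Pareto front inference and phylogeny-aware triangularity tests for
two-dimensional comparative trait data.

## The problem

When the evolution of a trait is shaped by several tasks that cannot be
optimised simultaneously, theory predicts that species fill a low-dimensional
polytope in trait space whose vertices are *archetypes* — phenotypes
specialised for a single task. A three-way trade-off leaves a triangular
footprint. The motivating application is sperm length (µm) versus body mass
(g) across tetrapods, both log10-transformed: do species fill a triangle, is
that triangle statistically distinguishable from a structureless cloud (also
after accounting for phylogenetic relatedness and uneven taxon sampling), and
which secondary traits — sperm competition proxies, clutch size, genome
size — are extreme near each vertex?

`paretofit` provides the full pipeline for researchers in comparative
biology and macroevolution:

* **Preprocessing** — `read_trait_table()`, `log10_traits()`,
  `relative_testes_mass()` (within-class log-log OLS residuals),
  `clutch_zscore()`, `subgroup()` (classes, endotherms, fertilization modes).
* **Geometry** — `fit_pcha()` (archetypal analysis) and `select_k()` to
  choose the number of archetypes; `fit_enclosing_triangle()`, an *exact*
  minimal-area enclosing triangle, to place them; `bootstrap_vertices()` for
  vertex uncertainty.
* **Inference** — the t-ratio statistic and permutation test:
  `t_ratio()`, `triangularity_test()`.
* **Phylogeny-aware nulls** — `sibling_tips()` (time-sliced leaf
  partitions), `sibswap_shuffle()`, `sibswap_curve()`,
  `modified_sibswap_test()` (tip averaging), plus
  `class_balanced_subsample_test()` and `fraction_subsample_curve()` for
  sampling robustness.
* **Enrichment** — `enrich_all()`: equally populated distance bins from each
  vertex and nearest-bin Welch t-tests.
* **Synthetic data** — `gen_triangle_cloud()`, `gen_cloud()`,
  `gen_enriched_feature()`, `gen_yule_tree()`, `gen_brownian_traits()`, so
  every stage is testable end to end without downloads.
* **Orchestration** — `run_full_analysis()` and `write_report()`.

## The core statistic

The **t-ratio** is

> t = area(best-fitting triangle) / area(convex hull of the data),

which approaches 1 for triangle-filling data and is markedly larger for
clouds, whose enclosing-triangle corners stay empty. Significance comes from
permutations: the p-value is the proportion of shuffled datasets (each trait
permuted independently — globally, within sibling tips of a time-calibrated
tree, or within classes) whose t-ratio falls below the observed one, with
p < 0.05 the conventional threshold. The triangle itself is the exact
minimal-area enclosing triangle (a deterministic stand-in for soft
minimum-volume simplex fits), so t ≥ 1 by construction.

## Worked example

```r
library(paretofit)

# a synthetic study: 1000 species uniform in a triangle in log-log trait
# space, with a clutch-size feature planted at the long-sperm vertex (T2)
pts <- gen_triangle_cloud(1000, seed = 42)
tab <- synthetic_trait_table(pts, features = list(
  clutch_size = pmax(1, round(25 * gen_enriched_feature(pts, default_triangle()[2, ],
                     amplitude = 2, decay = 1.5, noise_sd = 0.6, seed = 43) + 8)),
  testes_mass = 10^(0.7 * pts[, 1] - 1.2 + rnorm(1000, sd = 0.25))))
tab <- preprocess_trait_table(tab)

select_k(as_point_cloud(tab))$selected_k
#> [1] 3

(tri <- fit_enclosing_triangle(as_point_cloud(tab)))
#> Polytope with 3 vertices, area 7.34933
#>         x      y
#> T1 0.5052 1.2009
#> T3 7.9869 1.9020
#> T2 3.0007 3.3994

triangularity_test(as_point_cloud(tab), n_shuffles = 1000, seed = 1)
#> t-ratio permutation test of triangularity
#>   observed t-ratio : 1.0104
#>   null mean t-ratio: 1.6662 (1000 independent shuffles)
#>   p-value          : 0.004  (significant triangularity)

summary(enrich_all(tab, tri, features = c("clutch_z", "rel_testes_mass")))
#>                    vertex         feature    n      p_value direction
#> T1.clutch_z            T1        clutch_z 1000 2.019977e-03 minimized
#> T1.rel_testes_mass     T1 rel_testes_mass 1000 7.790201e-01      none
#> T3.clutch_z            T3        clutch_z 1000 2.601485e-22 minimized
#> T3.rel_testes_mass     T3 rel_testes_mass 1000 2.936301e-01      none
#> T2.clutch_z            T2        clutch_z 1000 9.709289e-29 maximized
#> T2.rel_testes_mass     T2 rel_testes_mass 1000 6.957033e-01      none
```

Reading the output: the SSE elbow over k = 2..5 picks three archetypes; the
fitted triangle hugs the hull (t-ratio 1.01, against a mean shuffled t-ratio
of 1.67), so triangularity is highly significant (p = 0.004 at 1000
shuffles); and the planted clutch-size gradient is recovered — maximized at
the long-sperm vertex T2, reduced near T1/T3 — while the unplanted testes
residual shows no enrichment anywhere.

For real data, point `read_trait_table()` at a species × traits CSV/TSV
(with a `column_map` if the headers differ), `read_timetree()` at a Newick
tree with branch lengths in Mya, and run `run_full_analysis(traits, tree)`
for the whole battery, serialised with `write_report()`.

## Documentation

The methods vignette (`vignettes/pareto-task-inference.Rmd`) describes the
model and its assumptions, the exact triangle solver, the elbow rule, the
permutation schemes (including the degenerate near-singleton SibSwap regime),
binning conventions, what the synthetic generators do and do not emulate, and
known limitations.
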