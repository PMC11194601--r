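# holcdiv

Historical "redlining" maps from the Home Owners' Loan Corporation (HOLC)
graded urban neighborhoods from A ("greenlined") to D ("redlined"), and those
grades still predict environmental quality today. `holcdiv` is an R package
for asking whether they also predict **wildlife biodiversity**: it links HOLC
neighborhood polygons to contributory (iNaturalist-style) species observation
records and quantifies how species richness and species composition vary
across grades, while controlling for neighborhood area, observation effort,
and urban intensity.

It is written for urban ecologists and environmental-justice researchers who
have (a) HOLC polygons in the Mapping Inequality GeoJSON dialect, (b) an
occurrence CSV, and (c) an impervious-surface raster — or who want to study
the statistical behavior of this analysis on synthetic data with known ground
truth, which the package generates itself.

## What it computes

**Accumulated species richness (collector's curves).** Per HOLC grade, the
cumulative count of unique species as observations accrue; a record of an
already-seen species adds to the observation count but not to richness. The
comparison statistic is the difference in observations (Δ) strata need to
reach the reference grade's maximum richness. A closed-form rarefaction
oracle gives the expected curve under random ordering,

```
E[S_k] = Σ_s ( 1 − C(N − n_s, k) / C(N, k) )
```

**Alpha diversity: a hierarchical Bayesian Poisson model.** For neighborhood
*i* in city *c(i)* with grade *g(i)*:

```
y_i ~ Poisson(μ_i)
log μ_i = log(area_i) + log(n_obs_i)            # exposure offset
        + b0 + u0_{c(i)}                         # city random intercept
        + b_{g(i)} + u_{g(i), c(i)}              # grade effect + city slope
        + b_imp · imperv_z_i                     # urban-intensity covariate
b ~ Normal(0, 2);  u ~ Normal(0, σ);  σ ~ Gamma(1, 1);  b_A ≡ 0
```

Fit by an adaptive Metropolis-within-Gibbs sampler (Rcpp) with a non-centered
parameterization and covariance-adaptive block updates; convergence is
checked with the Gelman–Rubin statistic (all R̂ < 1.10). Outputs are
per-neighborhood posterior predictions, grade-level richness summaries per
city and marginally over cities ("ALL"), and pairwise grade contrasts with
95% credible intervals on the response (species-count) scale.

**Beta diversity: Jaccard + PERMANOVA.** Presence–absence matrices, Jaccard
dissimilarity (0 = identical assemblages), PERMANOVA with sequential sums of
squares over (city, grade), permutation p-values (exhaustive enumeration for
tiny n), and within-city pairwise grade tests with Benjamini–Hochberg
correction.

**Synthetic data with known truth.** `make_region()` lays out rectangular
HOLC-like polygons with grade-ordered impervious cover on a raster;
`simulate_richness()` draws richness directly from the model above at chosen
parameters; `simulate_observation_records()` draws records from grade-nested
species pools with geometric rank-abundances, so every downstream stage can
be validated end to end.

## Worked example

```r
library(holcdiv)

out <- tempfile()
config <- run_config(
  out_dir = out,
  master_seed = 1,
  region = region_config(),        # 4 cities x 11 neighborhoods per grade
  community = community_config(),  # grade-ordered species pools
  mcmc_profile = "test",
  n_perm = 999
)
manifest <- run_pipeline(config)
cat(render_report(manifest), sep = "\n")
```

Selected lines of the report this prints (seed 1):

```
== Species richness by HOLC grade ==
city         grade  mean richness (95% CI)
ALL          A      36.63 (22.77, 56.48)
ALL          B      35.74 (9.48, 94.92)
ALL          C      20.69 (7.09, 47.67)
ALL          D      8.59 (3.02, 19.10)
...
-- Grade contrasts (response scale) --
A-D: 27.58 (14.30, 44.61) *
max Gelman-Rubin rhat: 1.0372

== Beta diversity (PERMANOVA, Jaccard) ==
city         df=  3  SS=   8.185  R2=0.1259  F=18.7927  p=0.0010
holc_grade   df=  3  SS=  32.298  R2=0.4967  F=74.1553  p=0.0010
```

Reading it: redlined (D) neighborhoods carry roughly a quarter of the
expected species richness of greenlined (A) ones after controlling for area,
effort, and impervious surface; the A–D contrast's credible interval
excludes zero (`*`); and both city and grade structure the species
assemblages (PERMANOVA R², F, with permutation p-values). The accumulation
section reports each grade's maximum accumulated richness and the
observation count needed to reach the reference grade's maximum; with the
generator's grade-ordered pools the lower grades never reach grade A's
maximum, so the effort disparity is read from the reverse comparison
(`compare_to_reference(curves, reference = "D")`): grade A reaches grade D's
maximum richness with about a hundred fewer observations.

Individual stages are plain functions over tibbles — `read_holc_geojson()`,
`read_observations_csv()`, `filter_records()`,
`assign_points_to_polygons()`, `richness_table()`, `build_model_data()`,
`sample_posterior()`, `summarize_grades()`, `grade_contrasts()`,
`build_presence_matrix()`, `jaccard_matrix()`, `permanova()`,
`pairwise_permanova()` — with `tidy()`/`glance()` methods and
`autoplot()`/`plot_grade_richness()` for figures.

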