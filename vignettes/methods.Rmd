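---
title: "Methods: models, generators, and numerical choices in holcdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators, and numerical choices in holcdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holcdiv)
```

`holcdiv` analyses the association between historical HOLC neighborhood
grades (A "greenlined" through D "redlined") and urban wildlife biodiversity
recorded by contributory platforms. This vignette is the package's account
of the statistical machinery: the models, the synthetic-data generator that
stands in for the real inputs, and the numerical decisions a reader would
otherwise have to reverse-engineer from the code.

## The richness model

The response is the number of distinct species observed in neighborhood $i$.
Observed richness scales with how much land is watched and how hard it is
watched, so the model treats neighborhood area times observation count as
exposure:

$$
y_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \underbrace{\log(\mathrm{area}_i) + \log(n^{obs}_i)}_{\text{offset}}
 + b_0 + u_{0,c(i)} + b_{g(i)} + u_{g(i),c(i)} + b_{imp}\, x_i .
$$

* $b_0$ — global intercept (log expected richness per km$^2$ per
  observation, at the reference grade and average urban intensity).
* $b_g$ — fixed effect of HOLC grade $g$; grade A is the treatment-coded
  reference, $b_A \equiv 0$. A value of $-1$ means grade-$g$ neighborhoods
  hold $e^{-1} \approx 37\%$ of the reference's expected richness at equal
  exposure.
* $u_{0,c}, u_{g,c}$ — city-level random intercepts and grade slopes,
  $u \sim \mathrm{Normal}(0, \sigma)$ with one $\sigma$ per effect type;
  these let the grade–richness association vary across cities.
* $b_{imp}$ — slope of impervious-surface cover, the urban-intensity
  covariate, per standard deviation. Impervious cover is z-scored over the
  modeled neighborhoods because the prior scale (below) presumes roughly
  unit-scale covariates; vegetation indices are deliberately not modeled, as
  impervious cover is their strong (negative) correlate.

Priors: fixed effects $\mathrm{Normal}(0, 2)$ (SD 2 — weakly informative on
the log scale); random-effect SDs $\mathrm{Gamma}(1, 1)$ (mean 1, decaying
density, strictly positive). Both are configurable via `prior_config()`.

Two readings of "area and observations, logged and summed" are possible for
the offset; `build_model_data()` defaults to
$\log(\mathrm{area}) + \log(n^{obs})$ — the standard product-exposure offset
— and exposes `offset_mode = "log_sum"` for $\log(\mathrm{area} + n^{obs})$.
Only $b_0$'s location depends on the area unit; rescaling every area by $c$
shifts $b_0$ by $-\log c$ and leaves the grade contrasts' significance
pattern unchanged (this is tested).

Neighborhoods with zero observations are excluded before modeling (the
offset is undefined at $n^{obs} = 0$); padding them with a pseudo-count was
rejected as an unstated manipulation of the data.

### Sampling

`sample_posterior()` runs an adaptive random-walk Metropolis-within-Gibbs
sampler written in C++ (Rcpp), in a **non-centered parameterization**:
deviations are sampled as $z \sim \mathrm{Normal}(0,1)$ with $u = \sigma z$,
which is mathematically identical to the stated model and keeps the sampler
stable when $\sigma$ approaches zero. Three classes of moves supplement the
componentwise updates, all chosen because the posterior has predictable
correlation structure:

1. **Translation moves** shift $b_0$ (or a $b_g$) while counter-shifting the
   corresponding city deviations, leaving the likelihood invariant; they fix
   the additive confounding between a fixed effect and its random
   deviations.
2. **Scale moves** multiply $\sigma$ while dividing its $z$'s, leaving every
   $u$ invariant (with the appropriate Jacobian), which decouples $\sigma$
   from the realized deviations.
3. **A covariance-adaptive block update** of the whole fixed-effect vector
   $(b_0, b_B, b_C, b_D, b_{imp})$, with the proposal covariance learned
   during burn-in (Welford running covariance, Cholesky refreshed every 100
   iterations, regularized by a small diagonal inflation). This matters
   because impervious cover is grade-ordered by construction, so $b_{imp}$
   and the grade effects are strongly collinear.

Proposal scales adapt toward 0.44 acceptance (componentwise) or 0.28 (block)
during burn-in only, in batches of 50 with diminishing gains, so the
post-burn-in chain is a fixed Markov kernel. Chains start from independent
over-dispersed prior draws (up to 100 retries for a finite posterior), all
randomness flows through R's RNG, and per-chain seeds derive from the master
seed, so runs are bit-reproducible. Linear predictors above 700 are rejected
outright to avoid overflow.

Two MCMC profiles exist: `"paper"` (110,000 burn-in, 40,000 retained, 4
chains) for full-length runs, and `"test"` (2,000 / 2,000 / 4) used by the
simulation studies; at the package's desk scale (176 neighborhoods) the test
profile reaches max $\hat R < 1.10$ routinely, which the convergence report
checks with the classic potential-scale-reduction formula
$\hat R = \sqrt{(n-1)/n + B/(nW)}$.

### Summaries and contrasts

Predictions and summaries are made on the response (expected species count)
scale, where the field reports them. City-level grade summaries average
$\mu_i$ over the cell's neighborhoods per posterior draw. The marginal
("ALL") level instead draws, per posterior draw, a *new* city — one shared
intercept deviation and one slope deviation per non-reference grade from the
fitted $\mathrm{Normal}(0, \hat\sigma)$ — evaluated at the grade's average
offset and covariate. Those intervals therefore include between-city
variance and are by construction wider than any within-city interval; the
ALL-level median is the robust location summary because the lognormal
new-city factor inflates means. Contrasts are draw-wise differences of
grade-level means, summarized by the median and the 2.5/97.5% quantiles;
"significant" means the interval excludes zero. No multiplicity correction
is applied across the six grade contrasts (correction is reserved for the
beta-diversity pairwise family, below).

## Accumulation and rarefaction

`accumulate_curve()` walks records in chronological order (ties broken by
record id) and increments the curve exactly at first sightings. The
accumulation order is genuinely ambiguous in this design — chronological is
the only order reconstructible from the data, so it is the default, and
uniformly permuted orders are available (`order = "permuted"`) both as a
robustness check and because their mean is known in closed form: the first
$k$ records of a uniform permutation are a uniform subsample, so the mean
curve equals the hypergeometric rarefaction expectation
(`expected_rarefaction()`). The exact standard deviation of subsample
richness (`rarefaction_sd()`) comes from per-species and pairwise joint
absence probabilities; it is the correct Monte-Carlo standard error for a
mean of permuted curves. The empirical SD of a finite set of curves is
exactly zero wherever the curve is deterministic (e.g. $k = 1$ and, without
singletons, $k = N$), so oracle checks use the exact SD.

The between-grade statistic is $\Delta$: the difference in observations
needed to reach the reference grade's maximum accumulated richness. A
stratum whose total richness is below the target is reported "unreached"
with a missing $\Delta$ rather than an extrapolation — Chao-type estimators
are out of scope. With the generator's grade-ordered pools the greenlined
stratum has the richest pool, so lower grades typically cannot reach its
maximum; the informative comparison is then the reverse reference
(`reference = "D"`), which measures how many fewer observations the
greenlined stratum needs to match the redlined stratum's maximum.

## Beta diversity

`jaccard_matrix()` computes $d = 1 - |A \cap B| / |A \cup B|$ on
presence–absence rows: 0 means identical assemblages, 1 disjoint. One
published description of this metric reads the endpoints the other way
around; the conventional dissimilarity direction is used here, and only the
direction — not any statistic — differs.

`permanova()` implements the distance-based ANOVA partition: Gower-centered
inner-product matrix $G = -\tfrac12 C D^{(2)} C$, sequential (Type-I) sums
of squares through incremental projection traces, pseudo-$F$ as the ratio of
term to residual mean squares, and p-values by free permutation of
neighborhood labels with the include-the-observed convention
$p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$, so $p > 0$ always. Term order
defaults to (city, grade), the order in which such analyses conventionally
report them; it is configurable. For $n \le 8$, `exhaustive = TRUE`
enumerates all $n!$ permutations and the p-value is exact. Comparisons of
$F^*$ against $F$ use a $10^{-12}$ slack so algebraically tied statistics
count as ties. On univariate Euclidean data the pseudo-$F$ reduces
algebraically to the classical one-way ANOVA $F$, which the tests verify to
$10^{-10}$ relative error against `aov()`, and the full two-term table is
cross-checked against an independent implementation of the same algorithm
(`vegan::adonis2`).

Pairwise grade tests run per city over the city's neighborhoods only, with
Benjamini–Hochberg correction across the (up to six) grade pairs within
that city — the family at which such pairwise results are reported. Pairs
with fewer than two neighborhoods in either grade appear in the table
flagged untestable, without a p-value and outside the BH family.
`bh_adjust()` delegates to `stats::p.adjust(method = "BH")` after validating
its inputs.

## The synthetic-data generator

The generator emulates the study system the pipeline is designed for — four
California cities, 44 HOLC-graded neighborhoods each, six animal clades,
heavy-tailed per-neighborhood observation effort, grade-ordered urban
intensity and richness — without any external download, and with every
generative parameter known.

**Regions.** Cities are laid out side by side; neighborhoods are
axis-aligned rectangles on a per-city slot grid (areas uniform on 0.5–3
km², aspect jittered), which keeps polygons non-overlapping and the
point-in-polygon join exactly testable while still exercising it. Impervious
cover is rasterized at 0.25 km cells: grade means default to 30/45/60/75%
(A→D) with SD 3 between neighborhoods and ±1 cell noise, so zonal means
recover the neighborhood value closely. Real HOLC polygons are irregular and
geodesic; users of real data must pre-project to a planar CRS — the package
is planar throughout by design, avoiding a geodesy dependency that the
synthetic frame does not need.

**Model-mode data** (`simulate_richness()`) draws richness directly from the
Poisson model at chosen `truth_params()`, with city effects either supplied
or drawn from their Normal distributions. Defaults
($b_0 = -1.5$, $b_B = -0.3$, $b_C = -0.6$, $b_D = -1.2$, $b_{imp} = -0.2$,
$\sigma_0 = 0.3$, $\sigma_{slope} = 0.2$) give a redlined-to-greenlined
richness ratio around $e^{-1.2} \approx 0.3$, the order of disparity the
pipeline is meant to detect.

**Record-mode data** (`simulate_observation_records()`) draws per-neighborhood
record counts from a negative binomial (mean 90, size 2 — heavy-tailed
effort), species from the neighborhood's grade pool with geometric
rank-abundance weights $(1-s)^{r-1}$ ($s = 0.02$, near-even), uniform
coordinates inside the rectangle, and uniform dates in the five-year study
window. Species pools are **nested across grades**: grade A's pool is drawn
first and each lower grade reuses a `pool_overlap` fraction (default 0.7) of
the adjacent grade's pool, *preserving those species' abundance ranks*, with
new species interleaved at random ranks. Rank preservation matters: with
full overlap and equal sizes the pools are then identical in both
composition and abundance structure, so neighborhoods are exchangeable
across grades and the PERMANOVA grade test faces a true null (its measured
size is checked to be nominal). Each pool is guaranteed at least one species
of every positive-weight clade — pool composition is shared across cities,
so a missing clade in one grade pool would make the grade-by-clade
city-inclusion rule unsatisfiable everywhere at once. A per-city fraction of
species (default 0.15) is relabeled city-endemic, identically across grades
within the city, creating between-city compositional structure without
disturbing within-city grade contrasts. Native/introduced status is assigned
once per species at pool creation, so a species' status is globally
consistent.

Default pool sizes are 120/60/26/10 (A→D). At the default effort this
yields adjacent-grade gaps of at least ~0.3 on the log-richness scale and a
greenlined-to-redlined expected richness ratio around 6. The gaps are chosen
so the generated ordering is *decisive*: with only four cities, the
random-slope structure leaves posterior medians of grade effects an
uncertainty of roughly 0.1 on the log scale, and a generator whose adjacent
gaps sit near that noise floor would produce data whose ordering the model
cannot reliably certify — a property of the design, not of the fitting code.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: spatial clustering of observers within
neighborhoods (records are uniform in the polygon), taxonomic
misidentification, temporal trends in platform usage, irregular and abutting
polygon geometry, spatially autocorrelated habitat, and the saturation
relationship between effort and richness (the model's linear-in-log-effort
offset is a deliberate simplification that real collector's curves violate
at high effort).

## Ingest rules

Filters apply in a fixed order — research-grade quality, species name
present, then the half-open date window `[start, end)` (the endpoint
convention is a decision; the five-year window's boundary day is excluded)
— and every rule's report satisfies retained + dropped = input, which is
fuzz-tested. The spatial join uses even–odd ray casting, boundary-inclusive;
a record falling in several polygons (shared edges, or overlapping real-world
polygons) is assigned to the lexicographically lowest neighborhood id with a
warning. A city is retained only if every grade-by-clade cell holds at least
five records (configurable), and dropped cities take their records with
them. Zonal impervious means average the raster cells whose centers fall
inside the polygon; sliver polygons that contain no cell center fall back to
the nearest cell to the polygon centroid, with a warning. Records with
unknown establishment status count toward overall richness but toward
neither the native nor the nonnative subset.

## Problem sizes and tolerances in the test suite

The simulation studies run at sizes chosen to make their statistical bands
meaningful: 50 replicates of the four-city region for posterior coverage of
the four fixed effects (coverage pooled over the $4 \times 50$ checks, since
per-parameter coverage at $n = 50$ is too coarse for a [0.90, 0.99] band);
500 exchangeable-null datasets at one city × six neighborhoods per grade for
the PERMANOVA size check; 20 end-to-end replicates for ordering recovery,
with the A–D contrast assessed within cities (the level at which pairwise
significance is conventionally reported; the marginal new-city contrast is
intentionally dominated by random-effect variance); and ten small
communities (7–12 records) of 200 permuted curves each for the rarefaction
oracle, where the every-$k$ three-standard-error band uses the exact
Monte-Carlo standard error and small communities keep the number of
simultaneous $k$ comparisons from inflating the familywise error of that
band. The GLM-limit check pins the random-effect SDs at $10^{-4}$ and uses a
covariate independent of grade, so prior shrinkage stays well below its 0.05
agreement tolerance with the IRLS fit.

## Known limitations

* Planar geometry only; no CRS handling.
* Exact-string species identity; no taxonomy resolution.
* The Poisson model carries no overdispersion or zero-inflation term; in
  record mode at high effort the offset is misspecified (see above), which
  the grade ordering tolerates but which would understate uncertainty on
  real, overdispersed data.
* PERMANOVA uses free permutations; no strata-restricted schemes or
  dispersion (PERMDISP) diagnostics.
* The "ALL" marginalization draws a single new city per posterior draw;
  with only four observed cities, $\hat\sigma$ is prior-sensitive and those
  intervals should be read qualitatively.
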