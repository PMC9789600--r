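---
title: "Age-spatio-temporal small-area estimation of deciduous caries indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-spatio-temporal small-area estimation of deciduous caries indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmftrend)
```

## The estimation problem

National child oral-health surveillance in many countries consists of a
handful of cross-sectional surveys spread over decades.  To report a yearly
national and provincial trend of the deciduous caries indices — dmft and its
decayed (dt), missing (mt) and filled (ft) components, each a mean count out
of the 20 primary teeth — every cell of a province × year × age-group × sex
lattice must be estimated although only a small fraction of cells carry
direct observations.  `dmftrend` implements a two-stage small-area
estimation pipeline for this situation, together with a synthetic-data
generator that emulates the sparse design so the whole pipeline can be
validated by simulation.

## Stage 1: covariate-driven mixed-effects model

For one index at a time, the observed cell means $y_{ptgs}$ (province $p$,
year $t$, age group $g$, sex $s$) follow a linear mixed model

$$y_{ptgs} = \mathbf{x}_{ptgs}^\top \boldsymbol\beta + u_p + a_t +
\varepsilon_{ptgs}, \qquad u_p \sim N(0, \sigma_P^2),\;
a_t \sim N(0, \sigma_T^2),\; \varepsilon \sim N(0, \sigma_\varepsilon^2),$$

with fixed effects for sex (indicator, reference `female`), mean years of
schooling, a standardised wealth index, the mean within-group age weight,
and age-group indicators, plus *crossed* random intercepts for province and
year.  Crossed (not nested) intercepts are the natural structure for a
province × year lattice: a year shock hits all provinces, a province offset
persists across years.  Estimation uses restricted likelihood via `lme4`
by default (`method = "ML"` available); the fixed design is checked for rank
deficiency up front, and fits with fewer than two provinces or years are
refused because the corresponding intercept variance is unidentifiable.
Indices are modelled on the identity scale — the data are mean counts, and
no link function is imposed — with clipping to $[0, 20]$ applied only at the
reporting stage.  Each of dmft/dt/mt/ft is fitted independently; no
additivity constraint is imposed, and reported component shares therefore
need not sum exactly to 100%.

Observations are equally weighted by default.  Inverse-variance weighting by
the reported standard errors is available (`stage1_spec(weighted = TRUE)`)
for data where the survey-level `se` is trusted.

Whether the first stage should be fitted separately per age group or jointly
was genuinely open; the default here is a joint fit with age-group
indicators plus the continuous age-weight covariate, which borrows strength
across groups while letting each group have its own level.  Stratified fits
can be obtained by subsetting the observations.

## Stage 2: age-spatio-temporal residual smoothing

Stage 1 predicts everywhere but ignores local structure; its residuals at
observed cells are therefore smoothed over the lattice and added back
(`smooth_residuals()`, `compose_estimates()`).  The smoother borrows
strength through three weighting components:

* **Spatial** $W_L \in \{0, 1\}$: 1 if two provinces are identical or share
  a border, else 0.  The self-weight of 1 is a deliberate choice — only
  cross-province weights are defined by the adjacency graph itself.
* **Temporal** $W_T = \left(1 - \left(\frac{|i-j|}{M}\right)^\lambda\right)^3$
  with $M$ the maximum absolute year lag plus one (28 for 1990–2017) and
  $\lambda = 2$ by default.  This is the tricube (LOESS-type) kernel in the
  scaled lag; taking $M$ as *max-lag-plus-one* keeps the weight strictly
  positive at the maximum lag, so distant surveys are down-weighted but
  never discarded.
* **Age** $W_A = e^{-\varpi |g-h|}$ over age-group positions, $\varpi = 1$
  by default; smaller $\varpi$ smooths more across age groups.

The combined weight of a source cell is the product $W_L W_T W_A$,
normalised to sum to one over all sources of the target's sex × index
stratum.  Normalisation is required for constant preservation (a constant
residual field must smooth to itself) and makes the smoother a
row-stochastic linear map.  When a target province has no same-or-adjacent
source (an isolated vertex), the spatial component is dropped for that
target and the temporal × age product used instead; such cells are flagged
`fallback = TRUE` in every output rather than left missing.  Sex is never
smoothed over.  $\lambda$ and $\varpi$ are fixed tuning constants, not
estimated from data.

## Uncertainty: parametric bootstrap for multilevel models

Percentile intervals come from resampling the fitted model
(`bootstrap_ui()`).  Replicate $b$ draws

1. $\boldsymbol\beta^{(b)} \sim \mathrm{MVN}(\hat{\boldsymbol\beta},
   \widehat{\mathrm{Cov}}(\hat{\boldsymbol\beta}))$;
2. each *fitted* random intercept from a normal centred on its predicted
   value with its conditional sd — uncertainty about the estimated effects,
   not fresh draws from $N(0, \sigma^2)$;
3. random-effect levels absent from the fit (years without any survey)
   from the fitted population distribution $N(0, \hat\sigma^2)$ of that
   term, since for those levels the fit carries no level-specific
   information;
4. a cell-level residual draw $N(0, \hat\sigma_\varepsilon)$ added to each
   replicate surface.  Without it the fitted residual sd could not influence
   interval width at all, and the intervals could not cover target surfaces
   that themselves carry cell-level variation beyond the smoothed signal.

When `propagate_smoothing = TRUE` (default) the residual smoothing is
re-applied inside each replicate; the kernel weights are deterministic, so
this is one precomputed matrix product per replicate block and costs little.
Bounds are empirical quantiles with linear interpolation between order
statistics (`stats::quantile` type 7, fixed for reproducibility), clipped to
$[0, 20]$.  `B` defaults to 1000; below 40 replicates a warning flags
unstable 95% endpoints.  The percentile construction does not guarantee
`lower <= point <= upper` and the package does not pretend it does; only
`lower <= upper` is asserted.

## Standardisation and derived summaries

`age_standardize()` performs direct age-standardisation: the weighted
average of age-specific estimates with the reference population's
normalised age shares, applied identically to the point and bound columns.
Standardising the bounds by the same linear map is a simplification; when
replicate draws are retained, the alternative — standardise each replicate,
then take percentiles — can be formed from the same machinery.  All-ages
rows in `make_trend_table()` aggregate the three age groups by population
shares (a crude unweighted mean is obtainable by passing equal weights);
display rounding is half-up to two decimals.  `percent_change()`,
`component_share()`, `experience_fraction()` (dmft as a share of 20 teeth)
and `provincial_range()` (sub-national divergence, ties broken by canonical
label order and flagged) cover the derived quantities of a trend report.

The packaged national table (`load_table1_fixture()`) contains published
point estimates and 95% bounds for 1990/2000/2010/2017 so that the
reporting operations have a realistic worked example; these numbers are
inputs, not outputs of this package's model.  The packaged census age
weights are a synthetic stand-in (labelled as such) with realistic relative
sizes of the 1–4, 5–9 and 10–14 cohorts.

## The synthetic-data generator

`generate_truth()` draws a complete latent surface from the generative
counterpart of the estimation model: linear predictor with the five named
fixed effects, province and year intercepts, *one* structured
province-year-age shock surface shared by both sexes, and cell-level noise;
dmft is clipped to $[0, 20]$ and split into dt/mt/ft by fixed proportions,
so additivity is exact by construction.  The structured field is white noise
pushed through the same kernels the estimator uses, mean-centred and
rescaled to a chosen marginal sd — so the estimator's smoothing assumptions
match the generator and parameter recovery is a fair test.  The field is
shared across sexes deliberately: a row-stochastic smoother of white noise
is dominated by a near-constant component, and independent per-sex fields
would hand each sex a large random offset that no fixed-effect estimator
could distinguish from the sex contrast.

Default conditions (fixed once, as the study conditions the generator
emulates): 31 provinces on a seeded geometric neighbour graph (mean degree
≈ 4–5), years 1990–2017, observed years
{1990, 1998, 1999, 2002, 2004, 2013, 2016} — five oral-health surveys plus
two multipurpose health surveys with oral modules — province coverage 0.9,
n = 400 children per cell, per-child sd 4 teeth (cell-mean noise sd
$4/\sqrt{400} = 0.2$), $\boldsymbol\beta$ = (3.5, +0.3 male, −0.1 schooling,
−0.3 wealth, +5 age weight), $\sigma_P = 0.5$, $\sigma_T = 0.2$,
$\sigma_\varepsilon = 0.5$, field sd 0.4, component split
(0.83, 0.10, 0.07) matching the published 1990 national shares.
`sample_observations()` fields a whole provincial survey at once (all ages,
sexes and indices of an included province-year), adds Gaussian noise on the
mean scale, and records the noise sd in `se`.  Its RNG stream is documented
(one inclusion draw, then one stacked noise draw) so realised sample counts
can be recomputed externally.

What the generator does **not** emulate: individual-level examination data
and within-survey design effects; measurement-protocol differences between
surveys; administrative-boundary changes over time (a static province list
is assumed, with case-insensitive label matching as the only aliasing);
non-Gaussian observation error for near-zero component means.  Passing
recovery and coverage tests therefore demonstrates internal consistency of
the pipeline under its own assumptions, not correctness of any real-country
estimate.

## Numerical choices and degenerate inputs

* Duplicate observation keys aggregate by the sample-size-weighted mean
  (`se` combined as $\sqrt{\sum (n_i\,\mathrm{se}_i)^2}/\sum n_i$);
  duplicates without `n` are an error, since no principled weight exists.
* Years outside the configured range are rejected, never clipped.
* Means outside $[0, 20]$ are a validation error with row numbers.
* Truth surfaces are clipped to $[0, 20]$ after assembly; clipping events
  are counted and reported when they exceed 1% of cells, because heavy
  clipping invalidates recovery experiments.
* The quantile rule (type 7), the spatial self-weight (1), the temporal
  normaliser (max lag + 1) and tie-breaking in `provincial_range()` (first
  canonical label, flagged) are fixed and documented rather than
  configurable.
* An indefinite fixed-effect covariance matrix aborts the bootstrap; an
  explicit `repair_vcov = TRUE` projects it onto the nearest PSD matrix.

## Validation experiments and their sizes

The test suite validates the pipeline at these scales, chosen as the
smallest sizes at which the Monte-Carlo error is clearly below the bands
being checked:

* kernel and smoother oracles: exhaustive small grids and random
  5 × 5 × 3 lattices against a brute-force triple loop (agreement to
  1e-12);
* stage-1 recovery: 200 replicates of the sparse design (30 provinces ×
  28 years × 3 ages × 2 sexes, 7 observed years); every fixed effect is
  recovered with well under 10% relative bias, and the pooled empirical
  coverage of the 95% Wald intervals for $\boldsymbol\beta$ falls in
  [90%, 98%].  Per-coefficient, the province-year-level covariate
  (schooling) sits at the anticonservative edge (~0.89–0.90): the
  structured field induces cluster-correlated residuals that model-based
  standard errors ignore.  This is a real property of model-based SEs under
  such designs and is reported rather than patched;
* bootstrap coverage: 200 synthetic truths with B = 500; the average
  fraction of lattice cells whose true dmft lies inside the 95% UI is
  ≈ 0.96–0.97, inside the [90%, 98%] band (mildly conservative at observed
  cells, where the estimate is close to the observation but the interval
  still carries the full residual sd).

`scripts/acceptance.R` re-runs the same quantities from scratch at 100
recovery replicates and 50 coverage truths, which reproduces the test-suite
values to well within Monte-Carlo noise in about a minute.

## Known limitations

Component fits are independent, so dt + mt + ft can drift from dmft in the
estimates (the generator keeps them exactly additive, so this drift is
measurable in simulations).  Smoothed bounds inherit the linear
standardisation simplification noted above.  The bootstrap treats the
kernel parameters and the adjacency graph as known constants.  National
aggregation defaults to an equal-weight province average; supply census
province weights for a population-weighted national series.
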