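---
title: "Extracting and comparing phenological metrics in phenowood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and comparing phenological metrics in phenowood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spring phenology in temperate deciduous woodland can be monitored in several
ways at once: ordinal bud scoring from the ground, leaf area index (LAI)
from hemispherical photography, crown greenness (NDVI) from multispectral
drone imagery, caterpillars intercepted in water traps beneath the canopy,
their frass caught in cloth traps, and end-of-season herbivory damage on
leaves. Each method produces a per-tree time series on its own scale.
Comparing trees, species and trophic levels requires collapsing each series
into a small set of comparable date metrics. `phenowood` implements that
collapse and the downstream comparison layer:

* **half-dates** — the day a tree's normalized trajectory crosses 0.5
  (budburst for bud scores, half-leaf for LAI, half-NDVI for greenness,
  half-fall for cumulative frass and caterpillar capture);
* **peak dates and heights** — the maximum of a fitted count intensity for
  the trap streams;
* **repeatability** of paired field measures (absolute-agreement ICC);
* **cross-metric** Spearman matrices and **cross-trophic** regression models
  (caterpillar timing on tree timing; herbivory on phenology), with variance
  explained, predictive-fit comparison (cross-validated ELPD) and Moran's I
  residual diagnostics.

Because the interesting guarantees are statistical (does the half-date
estimator find the right day? are its intervals calibrated? does the model
layer recover a known trophic linkage?), the package ships a synthetic
woodland generator with full ground truth, and its test suite is built
around parameter-recovery experiments on those woodlands.

## Normalization

Each tree x method series is rescaled to the unit interval before fitting:

* bud scores: `y = (score - 1) / (max_stage - 1)`, where the scoring key
  tops out at stage 5 for non-oaks and 7 for oaks. Visit-level scores are
  crown-section means, so fractional values are expected.
* LAI and NDVI: min–max within the tree's own series. A per-tree minimum is
  used for both streams; for NDVI one could argue for a fixed pre-season
  baseline instead, but a per-tree minimum is the choice here (it is robust
  to between-tree differences in understorey reflectance and winter
  canopy). A flat series leaves the metric undefined and is flagged.
* trap captures: cumulative proportion of the season total. Trees with a
  zero season total get an `undefined` flag and never a number — a real
  feature of such data, since some trees catch no caterpillars.

Normalization emits exact 0s and 1s; the Beta likelihood below is defined
on the open interval, so series containing boundary values are squeezed by
`y' = (y(n-1) + 0.5)/n` (n = series length) at fit time. The squeeze is
applied only when boundary values are present, so data already inside the
open interval are fitted untouched.

## Trajectory model and half-date extraction

The trajectory model is a Beta likelihood with logit link whose mean is a
penalized B-spline of day (second-difference penalty; smoothing parameter by
REML, i.e. marginal likelihood), fitted per tree with `mgcv`. Bud-score
streams may carry observer labels, which enter as a random intercept; the
extracted curve is the population-level one. A three-parameter logistic
(`ymax / (1 + e^{-k(t - t0)})`, nonlinear least squares) is available as a
fallback engine and is also used automatically if the Beta-GAM optimisation
fails, which happens on essentially noise-free series where the Beta
precision diverges.

Uncertainty is carried as an ensemble of `B = 500` replicate curves. The
default ensemble takes Gaussian draws from the coefficient posterior of the
fitted GAM using the smoothing-parameter-uncertainty-corrected covariance
(`vcov(fit, unconditional = TRUE)`). A parametric bootstrap (refitting on
Beta resamples) is available via `sigmoid_settings(ensemble = "bootstrap")`;
it gives similar intervals at roughly a hundred times the cost. Two
calibration choices were made by simulation: the corrected covariance and a
default basis dimension of 10. With the plain conditional covariance and a
smaller basis, 95% intervals for the half-date covered the truth for only
~88–90% of simulated trees; the defaults bring empirical coverage to ~91–92%,
comfortably inside the accepted band for a nonlinear functional of a
penalized fit.

The half-date is the first upward crossing of 0.5 of the central curve,
located on a 0.1-day grid and refined by root finding to 0.01 days; the
gradient at the crossing is a centred finite difference (h = 0.1 day). For
an exact logistic the half-date equals the midpoint `t0` and the gradient
equals `k/4`, which the tests assert to 0.05 days and 1e-3 respectively.
The 95% interval is the 2.5/97.5 percentile of the ensemble's crossing
days. Curves that never reach 0.5 are flagged `no_crossing`; curves already
above 0.5 at the first observed day are flagged `boundary`. If a
non-monotone fit recrosses 0.5 (plateaus from cold spells produce this in
real data), the first crossing is reported and `n_crossings` notes the
multiplicity.

Per-tree fitting is used throughout rather than a hierarchical
factor-smooth across trees of a species: every extracted quantity is
per-tree, per-tree fits are independently testable, and an optional
shrinkage (`sigmoid_settings(shrink = w)` plus a pooled species curve)
approximates the pooling a factor-smooth would give. The final-instar
winter moth stream is the sparsest and benefits least from flexibility —
exactly the stream for which individual smooths are the conventional
choice.

## Count curves and peaks

Trap counts are fitted on their raw scale with a Poisson-family GAM (log
link, same B-spline machinery). Frass mass is multiplied by 100
(gram to centigram) and rounded half-up to integers so the same count
machinery applies. Because interception traps accumulate between visits,
the default model includes `log(interval)` as an exposure offset, making
the fitted curve a per-day rate; `count_settings(exposure_offset = FALSE)`
disables this for strict per-visit modelling. An optional quasi-likelihood
scale factor handles overdispersion; the default is plain Poisson. The peak
day is the grid argmax of the central intensity (ties to the earliest day),
with a `boundary` flag when the argmax sits at the edge of the sampled
window — a monotone series peaks at the last visit and should not be read
as a dated maximum.

## Repeatability

`icc_absolute()` implements ICC(A,1): two-way model, single measures,
absolute agreement, from the mean squares of a units x measurements ANOVA.
Absolute agreement is the right variant for paired instruments (two
cameras, two traps under the same tree): a constant offset between
instruments is a real disagreement and lowers the coefficient, unlike a
consistency or Pearson coefficient. The consistency variant is exposed but
not the default. Single measures (rather than averages) are reported, since
downstream analyses use one instrument's data.

## The comparison layer

`spearman_matrix()` reports pairwise-complete Spearman correlations with
average ranks for ties, exact permutation p values for n <= 9 and the t
approximation otherwise, and each pair's own n (metrics go missing tree by
tree). Raw p values drive the default significance interpretation — matrices
of this kind are conventionally reported uncorrected — but a
Benjamini–Hochberg column is included.

`fit_cross_trophic_model()` regresses one caterpillar metric on one tree
metric plus sampling area (reference level "Great Wood"). Inference is
maximum likelihood; the default 95% intervals are t-based, which under the
Gaussian model are exactly calibrated and coincide with flat-prior Bayesian
credible intervals (a case-resampling percentile bootstrap is available,
and in simulation its intervals run one to two coverage points narrow at
n ~ 77). `fit_herbivory_model()` is the Beta-likelihood (logit link)
analogue for herbivory fractions, with a canopy-level random intercept via
`glmmTMB`; it defaults to Wald ML intervals because a bootstrap of a TMB
mixed model costs ~1000 fits for the same sign-and-coverage behaviour (the
bootstrap remains available via `ci_method = "boot"`). "Significant" means
the 95% interval excludes zero. Explained variance is
`var(fitted) / (var(fitted) + var(residual))`, with the model-implied mean
including the grouping effect for the Beta mixed model (a conditional R²).

Predictive comparison uses cross-validated ELPD: exhaustive leave-one-out
refitting for n <= 30 and seeded 10-fold cross-validation otherwise, with
plug-in predictive densities. The contract is the *ordering* of sibling
models sharing a response (`compare_models_elpd()` anchors the best at 0);
absolute values are not comparable across responses.

`morans_i()` computes Moran's I under row-standardized k-nearest-neighbour
weights (k = 8 by default — large enough to span the within-area grid
clusters the generator produces, small enough to stay local), with the
analytic null expectation -1/(n-1) and a two-sided permutation p (999
permutations). Exactly duplicated coordinates are collapsed to a single
site carrying the mean value, with a warning.

## The synthetic woodland

`woodland_config()` defaults describe the study system the package is
aimed at: six species (ash, beech, birch, hazel, oak, sycamore; 23, 5, 17,
30, 77 and 18 trees) whose mean budburst days span 31.9 days (hazel
earliest near day 100, ash last at day 131.9), per-tree half-date
deviations of sd 5 days, three sampling areas ("Great Wood", "ForestGEO",
"Marley") with small timing offsets and 100-m-grid spatial clusters, and
visits every 3 days with a 5% missed-visit probability over
method-specific windows.

Each tree has a latent logistic leaf-out trajectory (midpoint = its
half-date, rate ~0.30 logit units/day). Bud scores threshold the latent
proportion into equal-width ordinal stages (so the normalized mean score
crosses 0.5 at the midpoint, keeping the analytic identities available),
averaged over 12 crown sections with persistent section-level timing
spread and observer bias. LAI and NDVI are the same logistic lagged by 3
and 1 days, rescaled to realistic native ranges (0.6–3.6 effective LAI;
0.45–0.80 NDVI) with additive noise and a 2% outlier rate. Caterpillar
intensity is Gaussian in time with sd 6 days, centred at
`a + b t0 + area offset + noise` with defaults `a = 129`, `b = 0.20`,
residual sd 3 days; water traps accumulate intensity between serviced
visits and counts are Poisson. The winter moth substream is a binomial
thinning whose retention rises over the season, placing its peak ~1 day
after the total-count peak; frass biomass peaks 4 days before the count
peak. Herbivory is one Beta draw per oak with logit mean declining in the
tree's half-date at -0.07 per day. The within-tree observation-noise
magnitudes (LAI sd 0.12, NDVI sd 0.02, frass CV 0.25, section spread 2
days) are assumptions chosen to look like field data of this kind, not
estimates from any dataset; they are deliberately documented here as such.

What the generator does *not* emulate: weather-driven plateaus and cold
snaps (trajectories are cleanly sigmoidal), inter-annual structure,
species-specific caterpillar communities, spatially continuous phenology
gradients (space enters only through area-level offsets), or observation
failure modes beyond missed visits and symmetric outliers. Passing
recovery tests on these woodlands therefore demonstrates the estimators'
correctness and calibration under a realistic noise budget — not that any
particular field dataset satisfies the model.

## Numerical choices and degenerate inputs

* Evaluation grid 0.1 day; crossing refinement to 0.01 day by `uniroot`.
* Ensemble size 500 by default; interval extraction requires at least 20
  ensemble crossings, otherwise the CI is NA.
* The reported interval is widened, if necessary, to contain the central
  point estimate (the central curve is not an ensemble member).
* Fits refuse series with fewer than 5 distinct days, flat min–max series,
  all-zero count series, and flagged trajectories; these surface as flags,
  never numbers.
* Rounding to centigrams is half-up, documented, and tested (0.005 g is
  1 cg).
* All simulation, bootstrap and permutation randomness is seeded; the
  pipeline derives per-stage seeds from one top-level seed, and
  `generate_woodland()` restores the caller's RNG state.

## Problem sizes used in validation

The shipped validation suite runs parameter-recovery at the scale the
package is meant for: 100-tree woodlands for half-date and peak recovery
(with ensembles of 200), twenty replicate 77-oak woodlands for
cross-trophic slope recovery (true slope 0.20) with a permuted-predictor
null, twenty replicate 72-oak woodlands for the herbivory model (true
logit slope -0.07) with an ELPD ranking check against the intercept-only
model, and the full 170-tree default woodland for the structural ordering
check (frass half-fall before total-caterpillar half-fall before winter
moth half-fall in species means). Oracle-equivalence tests pin the ICC,
Spearman, Moran's I and ELPD implementations to independent brute-force
computations at 1e-10/1e-12 tolerances.

## Known limitations

* The modest spline basis means very short series (5–7 visits) fall
  back to the 3-parameter logistic, which cannot represent plateaus.
* ELPD uses plug-in predictive densities (no integration over parameter
  uncertainty), so it is slightly optimistic in absolute terms; only
  differences between sibling models are meaningful.
* The Beta mixed model's conditional R² uses the fitted-mean decomposition;
  with only three canopy levels the random-intercept variance is weakly
  identified and may collapse to zero.
* Min–max normalization propagates no uncertainty from the observed
  extremes into the half-date interval; at the default noise levels this
  costs a few coverage points, which the corrected covariance compensates.
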