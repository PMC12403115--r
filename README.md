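# phenowood

Phenological metric extraction and cross-trophic comparison for temperate
deciduous woodlands.

## The problem

Spring leaf-out and the caterpillar flush that follows it can be monitored
with several field methods at once — ordinal bud scoring, effective leaf
area index (LAI) from hemispherical photography, crown NDVI from
multispectral drone imagery, caterpillar water traps, frass traps, and
end-of-season herbivory scoring. Each yields a per-tree time series on its
own scale. Ecologists comparing trees, species, methods, or trophic levels
need each series collapsed into comparable **date metrics**, with honest
uncertainty, and then a statistical layer to relate them. `phenowood` is
that pipeline, aimed at quantitative ecologists working on tree–insect
phenological (mis)match.

## The statistics at its core

**Half-dates.** Each tree × method series is normalized to [0, 1] (bud
scores by the scoring key: y = (score − 1)/(max_stage − 1) with max stage 5
for non-oaks, 7 for oaks; LAI/NDVI by per-tree min–max; trap captures as
the cumulative proportion of the season total). A smooth trajectory is then
fitted per tree by maximizing a Beta likelihood with logit link,

  logit μ(t) = f(t),  y(t) ~ Beta(μ(t) φ, (1 − μ(t)) φ),

with f a penalized B-spline of day t (REML smoothing; mgcv). The
**half-date** is the day the fitted curve first crosses y = 0.5 (budburst,
half-leaf, half-NDVI, or half-fall depending on the stream), the gradient
at the crossing is extracted alongside, and a 95% interval comes from the
crossing days of an ensemble of posterior-draw curves. For an exact
logistic with midpoint t₀ and rate k this returns t₀ and k/4.

**Peaks.** Trap counts (frass in centigrams, ×100 and rounded half-up) are
fitted with a Poisson-family log-link spline of day; the **peak date** is
the argmax of the fitted intensity and the **peak height** its value, with
ensemble percentile intervals.

**Comparison layer.** Absolute-agreement intraclass correlation ICC(A,1)
for paired field measures; pairwise-complete Spearman matrices (exact
permutation p for n ≤ 9); Gaussian models of caterpillar metrics on tree
metrics with a sampling-area fixed effect; Beta-likelihood (logit link)
mixed models of herbivory with a canopy-level random intercept; variance
explained as var(fitted)/(var(fitted) + var(residual)); model comparison by
cross-validated ELPD (exhaustive leave-one-out for n ≤ 30); Moran's I on
residuals under row-standardized k-nearest-neighbour weights with
permutation p.

A synthetic-woodland generator (`generate_woodland()`) produces all streams
from known ground truth — species-structured budburst days spanning ~32
days, three observation streams of each tree's latent logistic trajectory,
accumulating water-trap counts around Gaussian seasonal intensities linked
linearly to host-tree timing, a thinned final-instar winter moth substream,
frass peaking ~4 days earlier, and herbivory declining with later
phenology — so every estimator is validated by parameter recovery.

## Worked example

```r
library(phenowood)

cfg <- woodland_config(
  species = data.frame(species = c("oak", "birch"), n_trees = c(8L, 5L),
                       mean_budburst = c(115, 104), max_stage = c(7L, 5L),
                       peak_abundance = c(30, 12)),
  seed = 42)
w <- generate_woodland(cfg)
w
#> Synthetic woodland: 13 trees, 1557 observations, 6 methods
#>         ForestGEO Great Wood Marley
#>   birch         1          0      4
#>   oak           2          2      4

# half-NDVI for one oak
obs <- w$observations
s <- obs[obs$tree_id == "T001" & obs$method == "ndvi", ]
traj <- normalize_minmax(s$day, s$value, "half_ndvi", tree_id = "T001")
extract_half_date(fit_sigmoid(traj, sigmoid_settings(B = 200)))
#>   tree_id    metric half_day   ci_low ci_high ci_width gradient_at_half flag
#> 1    T001 half_ndvi 122.2144 120.7984 123.628 2.829649       0.06072101   ok

# total-caterpillar peak for the same tree
cnt <- obs[obs$tree_id == "T001" & obs$method == "count_total", ]
extract_peak(fit_count_curve(cnt$day, as.integer(cnt$value),
                             count_settings(B = 200), tree_id = "T001",
                             metric = "tc_peak"))
#>   tree_id  metric peak_day peak_height height_ci_low height_ci_high flag
#> 1    T001 tc_peak    159.7    41.49162      36.88682       46.63536   ok

w$truth[w$truth$tree_id == "T001", c("half_date", "cat_peak_day")]
#>   half_date cat_peak_day
#> 1  120.7346     158.2969
```

The tree's latent half-date is day 120.7; its NDVI series lags it by the
configured 1 day and the estimate (122.2, CI 120.8–123.6) brackets the
truth. The count peak (day 159.7, expected catch ≈ 41/day at a 3-day
service interval) sits ~1.5 days after the true intensity peak because a
trap integrates the preceding interval — the documented accumulation
effect. `extract_metrics_table()` runs all nine metrics for every tree and
returns the wide per-tree table the comparison layer consumes, and
`run_pipeline()` orchestrates simulate → fit → compare → report with a
content-hash manifest.

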