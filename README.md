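# actiphen

Digital phenotyping of SSRI-associated movement patterns from week-long
actigraphy.

A hip-worn accelerometer summarizes gross motor activity as *vertical
acceleration counts per minute*; a week of wear gives 10,080 minutes per
participant. People taking selective serotonin reuptake inhibitors
(SSRIs) show a characteristic movement phenotype in such data: lower
overall activity, a shallower morning rise (6–9 am) and a shallower
evening decline (6–9 pm). `actiphen` implements the complete detection
analysis as a tested R package, for biostatisticians and digital-
phenotyping researchers who want to reproduce, stress-test or extend it:

* **Synthetic cohorts** with plantable effect sizes
  (`generate_cohort()`): overdispersed, zero-inflated minute counts
  around a piecewise-linear diurnal profile, exposure-correlated
  demographics, PHQ-9 scores with missing-at-random gaps.
* **Ingestion** of minute-record tables, medication tables (SSRI label
  derived from five generic-name stems) and PHQ-9 scores — tidy CSV or
  raw survey layouts (`read_cohort()`, `read_nhanes_cohort()`,
  `classify_ssri()`).
* **Preprocessing**: Savitzky–Golay smoothing, 7 × 24 × 60 week tensors,
  per-minute z-scores, stratified 80/20 + 10-fold plans, class weights
  (`smooth_week()`, `reshape_cohort()`, `standardize_per_minute()`,
  `make_fold_plan()`, `compute_class_weights()`).
* **Models**: a 6-level Daubechies wavelet-feature logistic baseline
  (49 features: mean, quartiles, entropy, SD, variance, mean-crossing
  rate per subband) and a from-scratch **ConvLSTM** classifier
  (ConvLSTM → max-pool → ConvLSTM → dropout 0.2 → dense → sigmoid) with
  class-weighted training and optional fusion of an imputed PHQ-9 score
  (`fit_wavelet_logistic()`, `train_cv()`, `impute_phq9()`). The
  backward pass is verified against finite differences in the test
  suite.
* **Attribution**: integrated-gradient per-minute attributions averaged
  across folds, 60-minute rolling summaries, and the per-minute Spearman
  correlation between movement and attribution
  (`compute_attributions()`, `summarize_attributions()`,
  `attribution_activity_correlation()`).
* **Statistics & metrics**: group activity means with CIs, morning and
  evening best-fit slopes with bootstrap CIs, χ²/Welch demographic
  contrasts, AUC (Mann–Whitney), Youden cut points, sensitivity /
  specificity / PPV / NPV, balanced accuracy, population stability index
  (`group_mean_activity()`, `interval_slope()`, `demographic_tests()`,
  `metrics_report()`).

Results come back as tibbles; fitted models support `tidy()` /
`glance()`; curves and attribution maps have `autoplot()` methods;
`run_pipeline()` drives everything end to end from a `run_config()` (or
a YAML file via `read_run_config()`).

## The core quantities

For exposure label $y_i \in \{0,1\}$ and minute counts
$x_i \in \mathbb{R}^{10080}$, the pipeline estimates

* group mean activity $\bar{A}_g = \tfrac1{n_g}\sum_{i \in g}
  \tfrac1{10080}\sum_m x_{im}$ (counts/min) with normal CIs;
* interval slopes: OLS fit of the day-averaged group curve on
  minute-of-day over [360, 540) and [1080, 1260), in counts/min²;
* $P(\text{SSRI} \mid x)$ from a class-weighted model — the weights are
  $w_- = n_+/n$, $w_+ = n_-/n$ — evaluated by Mann–Whitney AUC
  $P(s_{i^+} > s_{j^-})$ with fold t-intervals;
* per-minute additive attributions $\phi_{im}$ with
  $f(x_i) = f(\bar{x}_{\text{bg}}) + \sum_m \phi_{im}$ (integrated
  gradients, checked to 1e-3).

## Worked example

```r
library(actiphen)

# a 400-participant cohort with the default planted contrasts:
# amplitude ratio 0.71, slope ratios 0.75 / 0.51, prevalence 3.7%
coh <- generate_cohort(effect_config(seed = 1), 400)
coh
#> <ssri_cohort> 400 participants (15 exposed, 3.8%), 10080 minutes/participant
#>   PHQ-9 missing: 40.2%; mean activity 167.0 counts/min

gm <- group_mean_activity(coh$activity, coh$labels)
gm
#> # A tibble: 2 x 5
#>   group       n  mean ci_low ci_high
#>   <chr>   <int> <dbl>  <dbl>   <dbl>
#> 1 exposed    15  120.   120.    120.
#> 2 control   385  169.   169.    169.

curve <- group_curve(coh$activity, coh$labels)
interval_slope(curve, "morning", seed = 1)
#> # A tibble: 2 x 5
#>   group   interval slope ci_low ci_high
#>   <chr>   <chr>    <dbl>  <dbl>   <dbl>
#> 1 exposed morning  0.732  0.713   0.747
#> 2 control morning  0.971  0.968   0.975
```

The exposed group's mean (120 counts/min, vs 169 for controls — ratio
0.71) and its shallower morning slope (0.73 vs 0.97 counts/min², ratio
0.75) recover the planted effects. Classification on the same cohort:

```r
smoothed <- smooth_week(coh$activity)
plan <- make_fold_plan(coh$labels, 0.2, k = 10, seed = 2)
cw <- compute_class_weights(coh$labels[-plan$test])

fit <- fit_wavelet_logistic(wavelet_features(smoothed), coh$labels, plan, cw)
glance(fit)
#> # A tibble: 1 x 4
#>   cv_auc_mean cv_auc_low cv_auc_high test_auc
#>         <dbl>      <dbl>       <dbl>    <dbl>
#> 1           1          1           1        1

tensor <- reshape_cohort(standardize_per_minute(smoothed))
deep <- train_cv(tensor, coh$labels, plan, cw,
                 conv_lstm_desk_config(epochs = 3, seed = 3))
metrics_report(deep, "cv")  # AUC, cut point, sens/spec, PPV/NPV, BAC, PSI
```

Both models separate the groups perfectly here: the generator gives
every participant in a group the same diurnal profile, so the planted
29% amplitude contrast dwarfs the within-group variation of weekly
means. Real cohorts carry large between-person variability that the
generator deliberately omits (see the methods vignette), which is why
published AUCs on survey actigraphy sit in the 0.6–0.7 range.

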