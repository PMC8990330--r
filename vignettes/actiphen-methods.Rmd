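---
title: "Detecting SSRI exposure from week-long actigraphy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SSRI exposure from week-long actigraphy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Selective serotonin reuptake inhibitors (SSRIs) are associated with
movement-related side effects — fatigue, sleep disruption, blunted diurnal
rhythm — that are hard to capture with retrospective self-report. A
hip-worn piezoelectric accelerometer summarizes gross motor activity as
*vertical acceleration counts per minute*; one week of wear yields 10,080
minutes per participant. `actiphen` asks whether that week of passively
collected movement carries enough signal to detect SSRI exposure, and where
in the day the discriminating signal lives.

The package implements the full analysis as a reusable, tested pipeline:

1. a **synthetic cohort generator** with plantable effect sizes, so every
   downstream stage can be verified against a known ground truth;
2. **ingestion** of minute-level activity records, medication tables and
   PHQ-9 depression scores, in a tidy CSV exchange format and in the raw
   survey layouts (SAS transport files of the national health-survey
   actigraphy substudy);
3. **preprocessing**: Savitzky-Golay smoothing, reshaping each week into a
   sequence of 7 daily 24 x 60 hour-by-minute frames, per-minute z-score
   standardization, stratified splitting, class weighting;
4. a **wavelet-feature logistic baseline** and a **ConvLSTM classifier**
   (optionally fusing an imputed PHQ-9 score);
5. **temporal attribution** of the deep model's predictions back to minutes
   of the day;
6. **descriptive movement statistics**: group mean activity, morning and
   evening best-fit slopes, demographic contrasts; and
7. **evaluation**: AUC with fold confidence intervals, Youden cut points,
   confusion rates, balanced accuracy, and the population stability index.

## The synthetic cohort and what it emulates

`generate_cohort()` draws each participant's week around a piecewise-linear
diurnal profile: a night trough, a linear morning ramp over 6-9 am, a
daytime plateau, a linear evening decline over 6-9 pm, and a taper back to
the trough. The piecewise-linear shape is deliberate: the morning and
evening ramp slopes — the quantities the descriptive statistics estimate —
are planted *exactly*, so `interval_slope()` has a sharp ground truth.

The default `effect_config()` encodes the observed epidemiology of SSRI
use in a general-population actigraphy cohort:

* control 24-h mean activity 168.8 counts/min, with morning slope 0.97 and
  evening slope -0.76 counts/min² (counts per minute, per minute of clock
  time);
* exposed-to-control ratios 0.71 (overall amplitude), 0.75 (morning
  slope), 0.51 (evening slope) — i.e. the exposed group moves less and has
  blunter rest-activity transitions;
* exposure prevalence 3.7%;
* PHQ-9 depression scores (0-27, truncated negative-binomial with the
  variance-mean relationship of screening data) with a control mean of
  2.68 and a +1.58-point exposed shift, 40.2% missing at random given age
  and sex (younger and male participants are more likely missing, so the
  imputation stage is nontrivially testable);
* exposed demographics shifted older (mean 49.6 vs 33.1 years) and more
  female (69.9% vs 51.0%), with fixed race/ethnicity category
  probabilities per group.

Counts are nonnegative and overdispersed: negative-binomial draws
(dispersion `size = 5`) around the profile, with extra zero-inflation
(rate 0.3) during night minutes. The zero-inflated mean is compensated so
the marginal expectation at every minute equals the profile value — the
parameter-recovery tests depend on that identity.

What the generator does **not** emulate: between-participant
heterogeneity in overall activity (every participant in a group shares
one profile, so planted contrasts are far more separable than in real
cohorts — desk-scale AUCs saturate near 1 where field AUCs sit near
0.6-0.7), day-to-day autocorrelation and weekday/weekend structure
(every day shares one profile), wear-time artifacts and device nonwear,
survey sampling weights, and any causal structure linking depression to
movement. Passing tests therefore
demonstrate that the pipeline recovers what was planted under these
idealized conditions — not that the effects exist, or are estimable with
the same precision, in real cohorts.

## Preprocessing choices

**Smoothing.** A Savitzky-Golay filter (window 21 minutes, cubic,
configurable) denoises minute spikes while reproducing any polynomial
trend of degree ≤ 3 exactly, so the planted linear ramps pass through
unchanged. Edge minutes are handled by the filter's own boundary
least-squares fits rather than by padding: reflective padding of a
non-constant trend is no longer polynomial, which would break the exact
reproduction property at the week boundaries. On a bursty activity-like
test signal the filter's output SNR is about twice that of a moving mean
of equal width, consistent with its standard characterization.

**Reshaping.** `reshape_week()` maps minute *m* of day *d* to element
(d, h, m') of a 7 x 24 x 60 array, explicating within-day (hour, minute)
and across-day structure for the ConvLSTM; flattening is its exact
inverse. Axis order is (day, hour, minute).

**Standardization.** Each of the 10,080 minute-of-week positions is
z-scored across participants (population-SD convention, matching the
usual z-score normalization; a two-participant minute {1, 3} maps to
{-1, +1}). Constant minutes map to zero. The default computes statistics
on the full cohort — faithful to the original analysis — while
`train_idx` enables the leakage-safe variant (training-fold statistics
applied everywhere), which the property tests also exercise.

**Splitting and class weights.** `make_fold_plan()` holds out 20% per
class and assigns the remainder to 10 stratified folds; every subset's
class fraction deviates from proportionality by at most one participant
per class. With 266 exposed among 7,162, `compute_class_weights()` gives
each class the other class's prevalence (0.03714 for the majority, 0.96286
for the exposed class), enforcing a heavier penalty on errors in the rare
class.

## The wavelet-logistic baseline

Six levels of Daubechies decomposition (db4 by default; the order is not
dictated by the analysis being reproduced, so it is configurable) yield 6
detail subbands plus one approximation. Seven statistics per subband —
mean, 25th/75th percentiles, Shannon entropy of the normalized
squared-coefficient distribution (natural log), SD, variance, and the
mean-crossing rate — give 49 features per participant, fed to a
cross-validated logistic regression with per-observation class weights and
training-fold feature standardization.

Numerical conventions, each frozen by a test: the DWT follows the standard
half-sample-symmetric padding convention (verified coefficient-for-
coefficient against an independent reference implementation); a
`"periodic"` (periodization) mode is provided, under which the transform
is orthogonal and conserves energy exactly at even lengths — the energy
invariant is asserted in that mode, since symmetric padding conserves
energy only approximately. "Mean number of crossings" is read as
mean-crossings, `(number of sign changes of c - mean(c)) / (len - 1)`;
for zero-mean detail subbands this coincides with zero-crossings. All-zero
subbands have entropy 0 and crossing rate 0 by convention.

## The ConvLSTM classifier

The deep model consumes the standardized (7, 24, 60, 1) sequence — seven
daily frames, one LSTM time step per day, reducing the recurrence from
10,080 steps to 7 — through:

ConvLSTM(16 filters) → max-pool(2x2) → ConvLSTM(8 filters) →
dropout(0.2) → flatten → [concatenate z-scored PHQ-9, fusion variant] →
dense(16, tanh) → sigmoid.

The layer order and the dropout rate of 0.2 are fixed by the design being
reproduced; filters, kernels (3x3), pooling, dense width, the
adaptive-moment optimizer (learning rate 1e-3), batch size 32, epoch
budget and early stopping (validation-AUC patience) are unstated there and
are therefore package defaults, all overridable via `conv_lstm_config()`.
The dense hidden layer uses tanh: in a network this small a ReLU layer can
initialize with every unit inactive on an entire batch, silencing the
gradient entirely, and no part of the design pins the dense activation.
Training minimizes class-weighted binary cross-entropy. Gate order is
(input, forget, cell, output) with forget biases initialized to 1;
kernels are Glorot-uniform, seeded, so builds are bit-reproducible.

The implementation is native: same-padding convolutions via im2col + GEMM
and the cell nonlinearities live in compiled code, with backpropagation
through time orchestrated in R. The entire gradient — parameters and
inputs — is verified against central finite differences in the test suite,
which is the load-bearing correctness argument for everything downstream
(training, attribution).

The ten fold models each predict the held-out test set; the per-participant
test prediction reported alongside the per-fold runs is their average
(fold id 0). Test-set AUC intervals are computed across the ten fold
models' test AUCs, matching the "distinct model runs" reading; the
ensemble is the package's aggregation choice and per-fold reporting
remains available.

**PHQ-9 fusion and imputation.** Missing scores are imputed by iterative
regression on age, sex and race/ethnicity (single imputation,
deterministic; a chained-equations scheme degenerates to this when only
one variable has missingness). Observed values are never altered; imputed
values are clipped to [0, 27] with a report. The completed score is
z-scored on each training fold and concatenated into the dense layer's
input, adding exactly one fan-in (16 parameters) to the network.

## Temporal attribution

`compute_attributions()` produces per-minute additive attributions by
integrated gradients: for each fold model, the gradient of the predicted
probability is integrated along the straight path from a baseline (the
mean week of a seeded background sample of 100 training participants) to
the participant's week, by the trapezoid rule. The method satisfies the
additive-attribution axiom — baseline output plus summed attributions
equals the model output — up to integration error; with the default step
counts the tests hold this to 1e-3 (max-pooling makes the path only
piecewise smooth, so convergence is closer to first order than second;
the planted-window benchmark uses 128 steps). Attributions are averaged
elementwise across folds after the per-fold axiom holds; a failing fold is
excluded with a warning, and at least five folds (or all of them, if fewer)
must survive.

`summarize_attributions()` averages across participants and the seven days
to 1,440 minute-of-day values, then applies a centered 60-minute rolling
mean with edges truncated to the available support (day-averaging before
smoothing, matching the figure convention of the analysis being
reproduced). `attribution_activity_correlation()` computes, for every
minute of day, the Spearman correlation across participants between
day-averaged raw activity and day-averaged attribution, then the same
rolling mean; zero-variance minutes are recorded missing and excluded.

A related caution for null calibration: because early stopping restores
the epoch with the best validation AUC, the reported cross-validation AUC
is optimistically biased at the null (a max over noisy epoch draws). The
calibration benchmark therefore uses a small epoch budget and enough
positives per fold that this selection bias plus sampling noise stays well
inside the calibration band.

A caution from the benchmark: attribution concentration is a property of
a *trained* model. With very few optimizer steps a randomly initialized
ConvLSTM can separate classes through an aggregate of the signal while its
gradient field is still diffuse; the planted-window test therefore trains
for ~100 optimizer steps before asserting that top-decile attribution mass
concentrates in the planted window at three times the uniform share.

## Movement statistics

`group_mean_activity()` averages each participant's 10,080 minutes and
summarizes groups with a normal-approximation 95% CI over participant
means. `group_curve()` day-averages to 1,440 minutes, smooths each
participant curve (the filter is linear, so the group mean is unaffected
by the order of smoothing and averaging), and reports pointwise CIs.
`interval_slope()` fits OLS on the group curve over the half-open windows
[360, 540) (6-9 am) and [1080, 1260) (6-9 pm) — units counts/min², raw
counts rather than z-scores — with a seeded participant-level bootstrap
(default 1,000 resamples) for the CI. The bootstrap source of variation is
the package's choice (the original analysis does not state one), so slope
*point estimates* are the comparable quantity, not CI widths; a coverage
test over 150 synthetic replicates checks the intervals cover planted
slopes at least 90% of the time.

Demographic contrasts use the chi-squared test for sex and race/ethnicity
and the two-sided Welch (unequal-variance) t test for age and PHQ-9 —
Welch because group variances genuinely differ and the design says only
"t test". `welch_t_summary()` evaluates the same test from printed
summary statistics, letting published cohort tables be checked without
unit-level data.

## Evaluation

AUC is Mann-Whitney concordance with ties counted one half, computed from
ranks and tested against brute-force pairwise enumeration. Fold AUCs are
summarized by mean and 95% t-interval. The cut point maximizes Youden's
J on each fold's validation predictions (ties toward the lower threshold;
midpoint of the gap under perfect separation; 0.5 with a warning for
degenerate constant scores) — a rule consistent with near-prevalence
baseline cut points under heavy imbalance. Confusion rates are reported
with PPV/NPV as percentages and BAC = (sensitivity + specificity)/2. The
population stability index bins both score samples by the deciles of the
reference (training-fold) distribution and sums
`(p - q) log(p / q)` with proportions floored at 1e-4; it is nonnegative,
zero iff binned proportions agree, and invariant to monotone score
transforms. PSI conventions differ enough across the literature that the
package validates PSI only against its own definition, never against
published values on other scales.

## Problem sizes

The test suite and the acceptance script run everything at desk scale, a
deliberate set of package defaults: parameter recovery on a 2,000-
participant cohort; model calibration and signal-detection checks on
400-participant cohorts with the reduced ConvLSTM profile (8/4 filters,
≤ 10 epochs); the attribution benchmark on 200 participants with 5 folds.
Full-scale settings (16/8 filters, 50-epoch budget, cohorts in the
thousands) are configuration presets, not test requirements.

## Known limitations

* The generator's days are exchangeable; models that exploit day-of-week
  structure cannot be probed with it.
* Single imputation understates PHQ-9 uncertainty; the multiple-imputation
  spread is not propagated into AUC intervals.
* Integrated gradients is one member of the additive-attribution family;
  other explainers (sampling-based Shapley estimators in particular) may
  distribute mass differently while satisfying the same axiom.
* The optional raw-survey ingestion path maps the documented table
  layouts; the exact completeness rule by which the original cohort of
  7,162 reliable wearers was defined is not published, so the completeness
  policy is explicit and configurable (`strict-drop` by default) rather
  than claimed to match.
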