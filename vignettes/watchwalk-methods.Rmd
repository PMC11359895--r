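---
title: "Wrist-worn accelerometry to daily-life gait and sleep biomarkers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-worn accelerometry to daily-life gait and sleep biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watchwalk)
```

## The problem

A wrist-worn tri-axial accelerometer sampled at 100 Hz records a week of a
person's life. From that single stream, `watchwalk` derives twenty daily
gait and sleep biomarkers spanning six domains: sleep (duration, bedtime),
gait quantity (steps per day), walk-length distribution (longest continuous
walk, proportion of walking time in bouts of at least 8 s and 60 s), gait
speed (maximal and usual walking speed), gait quality (cadence median and
IQR, step-time variability, step and stride regularity) and walking hand
positions (percentages of walking with arm swing, texting, phone call,
hands in pockets, shoulder bag, briefcase, plus the static and adaptive
groupings). The cohort layer adds wear-time inclusion criteria, sex- and
age-stratified normative percentile tables, standardized (z) biomarker
profiles and test-retest reliability.

The wrist is a convenient but indirect vantage point: arm movement is only
loosely coupled to the legs. The pipeline therefore first decides, window
by window, *what the arm was doing* (a two-stage activity classifier over
hand positions) and only then measures gait inside windows recognized as
walking.

## Signal path

1. **Magnitude and filtering.** The per-sample Euclidean norm of the three
   axes removes first-order orientation dependence. The norm is bandpass
   filtered to 0.25–2.5 Hz with a 5th-order Butterworth characteristic,
   applied zero-phase (forward–backward) so that step-event timing is not
   shifted. The filter is realized as a cascade of a 5th-order high-pass at
   0.25 Hz and a 5th-order low-pass at 2.5 Hz rather than a single
   bandpass polynomial: at a 100 Hz rate the equivalent 10th-order bandpass
   transfer function has pole moduli of about 0.994 and visibly leaks DC in
   double precision, while the cascade attenuates a constant input below
   1e-7 g and matches its closed-form magnitude response to better than
   0.1%. The closed form of the cascade is what the filter tests check
   against. Whether the original implementation filtered causally or
   zero-phase is not documented; zero-phase is the choice here, recorded
   once and relied on everywhere downstream.

2. **Windowing.** Non-overlapping 4-second windows; a trailing remainder is
   discarded; timestamp gaps longer than 1.5 sampling intervals are treated
   as recording breaks that windows never span. Recordings at other rates
   are linearly resampled to the configured rate on reading, so feature
   semantics are fixed.

3. **Features.** Each window yields 54 features. The dimensionality and the
   RBF kernel coefficient gamma = 1/54 are binding constraints; the
   identity of the original 54 features is not recoverable, so the set here
   is a fixed, versioned re-design (`feature_names()`): time-domain
   statistics, band powers over 0.25–0.75/0.75–1.25/1.25–1.75/1.75–2.5 Hz,
   spectral shape, autocorrelation peak value and lag of the filtered
   magnitude; per-axis summaries of the raw axes; correlations, RMS and
   zero crossings of the filtered axes; jerk; raw-magnitude and
   static-removed-magnitude summaries. Model weights trained against any
   other 54-feature set will not transfer, which is why every persisted
   model carries a feature-version tag that prediction checks.

4. **Classification.** Stage 1 labels each window as walks-with-arm-swing,
   other complex walking, running, stationary, unspecified arm activity
   while sitting/standing, or unspecified arm activity while walking, with
   class weights 50/25/10/5/5/5 concentrating the decision boundary on
   walking. Stage 2 splits other-complex-walking into hands-in-pockets,
   hands-held-stationary (texting), hand-next-to-ear (phone), hand-on-
   shoulder and briefcase/grocery-bag, with uniform weights (stage-2
   weights are not specified anywhere; uniform is the neutral choice).
   Both stages are RBF-kernel SVMs (via libsvm's one-vs-one decomposition,
   which realizes per-class weighting by scaling the cost C per class).
   Features are z-scaled with parameters fitted on training folds only —
   gamma = 1/54 is only meaningful on commensurate scales. The cost
   parameter is not specified in the source method; C = 1 is used and
   recorded in model metadata. Cross-validation is always partitioned at
   the participant level: participants are shuffled by a seeded RNG and
   dealt round-robin into 10 folds, so no subject's windows straddle a
   fold; with fewer than 10 participants this degrades to
   leave-one-participant-out.

5. **Walking bouts.** Windows labelled with either walking class form
   candidate runs; a pause between two runs is bridged when it (1) is at
   most 60 s, (2) does not exceed either neighbouring run, and (3) does not
   exceed one fifth of at least one neighbour. Criteria (2) and (3) admit
   several readings; the implemented one — (2) as a min bound, (3) as a
   max/5 bound — is the only one in which the two criteria are mutually
   non-redundant for unequal neighbours. Bridging is applied iteratively
   left-to-right with re-evaluation after each merge, because a merged run
   legitimately lengthens a neighbour and can enable the next merge; the
   fixed order makes the result deterministic. Bridged pause time counts
   toward bout duration but contributes no steps. The exposure biomarkers
   are the percentage of total walking time contributed by bouts of at
   least 8 s and at least 60 s.

6. **Steps.** Candidate steps are peaks of the filtered magnitude with
   spacing of at least 0.25 s and prominence of at least a quarter of the
   window RMS. The window must also exhibit an autocorrelation peak (lag
   searched in 0.25–1.0 s) of at least 0.3, and the median inter-peak
   interval must match that period within ±20% at the step or stride lag —
   otherwise the window contributes no steps. The 0.3 threshold sits far
   below genuine gait (typical step regularity 0.5–0.7) and roughly six
   sampling standard deviations above what iid noise produces in a 400-
   sample window. Wrist-invisible walking (arms pushing a pram, carrying
   rigid loads) is handled by the corrective step count: the mean
   ground-truth steps per unspecified-arms-walking window, estimated at
   training time, times the number of such windows.

7. **Episodes, cadence, variability.** Consecutive steps (intervals up to
   2 s) regroup into non-overlapping 8-step episodes; the trailing partial
   episode is discarded. An episode spans 7 intervals, so cadence is
   60·7/(t8 − t1) steps/min; the episode's step-time SD comes from those
   intervals. Daily cadence is the median (and IQR) over episodes; daily
   step-time variability is the 95th percentile of episode SDs. All
   percentiles in the package — this one, maximal speed, normative tables —
   use one quantile rule: linear interpolation between order statistics
   (type 7).

8. **Regularity.** The unbiased, lag-0-normalized autocorrelation (dividing
   lag k by n − k) is exactly 1 at the period of a perfectly periodic
   signal, which makes the "1 = perfectly repeatable gait" anchor exact.
   Step regularity is the coefficient at the first dominant peak (step
   period), stride regularity at the second peak near twice that lag
   (±25%). Windows without a qualifying peak are flagged missing. Daily
   values aggregate by the mean over walking windows (the aggregation
   policy is isolated behind an argument; median is available).

9. **Speed.** Only arm-swing windows with detected steps are scored, using
   eight predictors in fixed order: sex, body height, median and IQR of the
   static-removed magnitude (max(norm − 1 g, 0), an ENMO-style dynamic
   component), mean raw magnitude, mean step time, and x–y / x–z
   correlations of the bandpass-filtered axes (unfiltered correlations
   would be dominated by gravity). The regressor is an RBF-kernel SVR with
   gamma = 1/8 — one over the number of predictors, mirroring the
   classification convention — and library-default cost and epsilon,
   recorded in metadata. Training rows are put into a canonical order
   before fitting so the model, not just the fold assignment, is invariant
   to permutations of the input windows. Daily maximal and usual speeds are
   the 95th percentile and median of the day's predictions; only arm-swing
   windows contribute, matching the predictor definition.

10. **Sleep.** A deliberately simplified variant of the published arm-angle
    family of algorithms: the elevation angle atan(z/√(x²+y²)) on 5-s
    rolling medians; runs where successive epochs change by less than 5°
    for at least 5 minutes count as sustained inactivity; runs separated by
    less than 60 minutes chain into blocks; the longest block per
    noon-to-noon day is the sleep period, its span the duration, its onset
    the bedtime. No diary anchoring, no multi-block nights. The noon-to-noon
    boundary avoids splitting a night across calendar days, and bedtimes
    aggregate across days by circular mean on the 24-h clock.

11. **Wear time and inclusion.** Non-wear is a 60-minute block (evaluated
    per 15-minute epoch) with per-axis SD below 13 mg on all axes. A
    "complete" day is operationalized as at least 23 wear hours (the
    source criterion never defines "complete"; the threshold is in the
    configuration). Inclusion: five complete days (strict) or three days
    with twelve wear hours (relaxed).

12. **Cohort layer.** Per-subject pooling over included days uses the mean
    for approximately normal markers and the median for the skewed ones
    (longest walk, % walks ≥ 60 s, hand-position percentages) — the skew
    classification is fixed in code, not re-estimated from data. Normative
    tables report the 5/10/25/50/75/90/95 percentiles per biomarker within
    sex × age group (45–54, 55–64, 65–74, 75–79; left-closed edges;
    subjects outside [45, 80) are excluded). z-profiles standardize a
    subject against a reference cohort, flipping the sign of
    lower-is-better markers (step-time variability) so positive always
    means better. Reliability across monitoring days uses ICC(2,k) —
    two-way random effects, absolute agreement, average of k measures —
    computed from the two-way ANOVA mean squares, with F-distribution 95%
    bounds (single-measure limits with Satterthwaite degrees of freedom,
    stepped up by Spearman–Brown). Rows with missing days are dropped,
    complete-case, because the absolute-agreement formulas assume a
    complete two-way layout.

## The synthetic-data generator

Real normative data of this kind comes from access-restricted cohorts, so
the package ships a generator that plays the role of both the development
study and the cohort: scripted schedules of activities with per-sample
ground truth (labels, step events, true speeds, sleep intervals).

What it emulates, and how:

* **Gait.** Step events are laid down at the scheduled cadence with
  Gaussian step-time jitter; the step count is a deterministic function of
  duration and cadence, never of the noise seed. Each step contributes a
  Gaussian impact bump (σ = 60 ms) along the gravity axis; the arm swings
  as a sinusoid at stride frequency whose amplitude depends on the hand
  position (largest for arm swing, strongly damped for texting/phone) and
  on speed.
* **The speed → signal map.** True speed enters through two monotone
  channels: cadence (via a speed- and height-dependent step length,
  `cadence_from_speed()`) and amplitude (impact and swing amplitudes scale
  with 0.4 + 0.5·v). This gives the speed regression a learnable target
  without dictating its functional form.
* **Hand positions.** Each stage-2 class has a distinct wrist orientation
  (gravity direction), swing amplitude and impact size, so the classes are
  genuinely separable — by design, since the purpose is to exercise the
  two-stage classifier, not to claim biomechanical fidelity.
* **Rest, sleep, posture.** Stationary rest holds a posture for 1–4
  minutes between shifts; sleep holds one for 20–45 minutes between
  turns; successive postures always differ by at least 10° of elevation,
  so a posture shift reliably breaks a sustained-inactivity run. During
  dynamic activity the gravity direction wanders slowly as a rotation
  (magnitude-preserving, so norm-based features are untouched), keeping
  the 5-s median arm angle moving as on a real wrist.
* **Cohorts.** Subjects draw sex (balanced), height (normal by sex), age
  (uniform 45–79) and a usual walking speed with a male offset, an
  age-related decline and individual variation; day-to-day speed varies
  within subject by a configurable fraction. For reliability studies a
  separate generator draws subjects × days matrices from the two-way
  random-effects model with the residual variance solved so the population
  ICC(2,k) equals a requested value.

What it does **not** emulate — and therefore what green tests do not show:
biomechanically valid gait (no double support, no left/right asymmetry),
terrain and environment effects, device calibration error, non-wear that
looks like sleep, naps, and the long tail of ambiguous real-life arm
activities. Classifier accuracies near 100% on this generator demonstrate
that the pipeline machinery is correct, not that these accuracies transfer
to field data.

## Numerical choices and degenerate inputs

* One quantile rule everywhere (linear interpolation, type 7).
* Constant windows: dispersion features are exactly 0 (a DC-only segment
  has zero in-band content by construction); correlations with a constant
  are defined as 0; skewness/kurtosis of a constant are 0.
* Windows with no detectable period return no steps and missing
  regularity rather than garbage values; days without walking carry
  missing gait biomarkers — missingness is data, not an error.
* ICC with zero residual variance returns exactly 1 with a degenerate
  interval; zero walking time leaves exposure proportions missing rather
  than 0.
* The bridging rule oracle (three explicit inequalities) is kept separate
  from the implementation so the documented interpretation of the criteria
  can be swapped if evidence about the original reading emerges.

## Problem sizes in the shipped tests

The test-suite and acceptance cohorts are sized for a laptop-class single
core: 20 subjects × one scripted session at 100 Hz for classifier and
speed-model recovery; one free-living noon-to-noon day for the end-to-end
checks, generated at a 20 Hz configuration (the pipeline is rate-agnostic
above twice the 2.5 Hz band edge, and a full day at 100 Hz buys no
methodological coverage); 100 subjects × 7 days × 10 replicate cohorts for
ICC recovery. These sizes are the package's choices for its own
verification and are stated here so results can be reproduced exactly.

## Known limitations

* The 54-feature set is a faithful-dimensional re-design; weights from
  other implementations will not transfer.
* The sleep estimator is a simplified variant; it reports one block per
  noon-to-noon day and will under-report badly fragmented nights.
* Step-time variability inherits detection dropouts: a missed step inside
  an episode inflates that episode's SD, and the daily 95th-percentile
  rule deliberately looks at the worst episodes.
* Hand-position percentages are conditional on the classifier; on real
  data their errors are correlated with classification errors.
* The wear-time heuristic cannot distinguish a perfectly still worn device
  from an unworn one inside a single 60-minute block.
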