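---
title: "Methods: from wearable beat streams to per-day sleep-quality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable beat streams to per-day sleep-quality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvsleep)
```

## The analysis in one paragraph

`hrvsleep` implements a complete chain from raw wearable recordings to
interpretable models of self-reported sleep quality. Interbeat intervals
(IBIs) from an arm-worn optical sensor are cleaned of detection artifacts,
cut into non-overlapping 5-minute windows, and summarised by the Poincaré
descriptors SD1, SD2 and SDNN. Nights are located from heart rate, motion
and steps; transition hours are trimmed; windows are aggregated into one row
per participant-day (minimum, mean, maximum, and min/mean and max/mean
ratios per variable and wake/sleep state, plus diary variables). Every
feature and the 1–5 morning rating are then z-scored *within participant*,
the rating is binarised at the personal average, and L1-penalized logistic
models estimate which within-person changes move the odds of a
better-than-usual night. Evaluation uses repeated, perfectly balanced,
subject-held-out test sets. Because studies of this design rarely release
raw data, the package ships a synthetic cohort generator with known ground
truth for every stage; all quantitative claims about the pipeline are made
against that truth.

## Signal processing

**Artifact model.** Two corruption classes dominate wearable IBI streams:
*missed beats* (two intervals fuse into one of roughly double length) and
*ectopic / spurious detections* (one interval splits in two). The detector
flags beats whose interval deviates from a running median of
`window_beats = 5` neighbours by more than `criterion_mult = 3.32` quartile
deviations of the successive differences. The 3.32 multiplier is the
conventional value for quartile-deviation-based beat editing; the narrow
5-beat window matters because beat series are strongly autocorrelated — a
wide window tracks the slow heart-rate trend poorly and inflates the false
positive rate several-fold. The quartile deviation is floored at
`qd_floor_ms = 10` ms so a metronomically regular stretch cannot drive the
criterion to zero. Flagged beats are linearly interpolated between valid
neighbours and marked, and any 5-minute window with five or more
interpolated beats is discarded. On synthetic streams with 2% injected
artifacts the defaults give sensitivity ≥ 0.9 at a false positive rate
≤ 0.02 (measured in the test suite against generator truth).

**Windows and descriptors.** Windows tile the recording from its first beat
timestamp in 300-second steps, half-open `[start, end)`, beats assigned by
interval end-time, trailing partial window dropped. Whether the original
study aligned windows to the clock or the recording is not stated; recording
alignment is implemented because it is parameter-free. Descriptors use the
*population* SD over each window's pairs: with consecutive pairs
\((x_i, x_{i+1})\),

$$\mathrm{SD1} = \mathrm{SD}\!\left(\tfrac{x_{i+1}-x_i}{\sqrt2}\right),\quad
  \mathrm{SD2} = \mathrm{SD}\!\left(\tfrac{x_{i+1}+x_i}{\sqrt2}\right),\quad
  \mathrm{SDNN} = \mathrm{SD}(x_i),$$

equivalent to the SDs of the distances from the +45° and −45° lines of the
Poincaré plot (the test suite checks this equivalence against an explicit
point-to-line oracle at 10⁻⁹ ms).

**Resting filter.** HR/HRV windows enter the daily aggregates only when mean
HR is strictly below 0.55 × (220 − age) bpm, the standard eligibility rule
for photoplethysmography-based HRV. Whether the original analysis applied it
to sleep windows too is unstated; the package applies it to both states by
default (`resting_sleep = TRUE`), switchable in configuration.

**Sleep segmentation.** The study this design follows labelled nights
manually; the package automates it so that it is reproducible and its error
is measurable. A second is a candidate sleep second when the 10-minute
rolling median of accelerometer magnitude lies in the lower quarter of its
q10–q90 range, the rolling 10-minute step count is zero, and the rolling
median heart rate is below the midpoint of its q10–q90 range. Range-based
thresholds (rather than a fixed quantile of the whole day) separate the
night and day modes regardless of what fraction of the record is sleep.
Interruptions up to 30 minutes are bridged; the longest block of at least
3 h wins; there is a no-sleep-found error otherwise. On default synthetic
nights the estimator recovers bed and wake times with a median absolute
error of roughly a quarter hour (asserted ≤ 30 min in the acceptance
tests). One hour after bed time and one before wake time are excluded from
the sleep state — exactly 2 h per night — and windows touching those zones
belong to neither state. Days are wake-anchored: day *d* runs from wake *d*
to wake *d+1*.

**Normative transform.** Published HRV norms by age, sex and time of day are
not reprinted here, so the normative table is an input
(`normative_table()`, CSV-backed). The package bundles an identity table
and `build_normative_table()`, which derives strata from a reference
cohort's own windows; both are clearly synthetic stand-ins, not published
norms.

## Modelling

**Within-person normalization.** Each retained column is z-scored per
participant with the n−1 SD (small per-person samples make the sample SD the
conventional choice). Person-constant columns are dropped for that
participant and recorded; participants with fewer than two non-missing days
are dropped with a warning. Models on this scale explain *within-person
change*; between-person level differences are deliberately removed.

**Binary response.** The normalized 1–5 rating is discrete and fails the
Shapiro–Wilk normality gate (`check_response_normality()` reports this and
the justification), so the response is the indicator of a night strictly
better than the participant's average; a night exactly at the average
counts as low ("better" is strict).

**Penalized model family.** The lasso performs feature selection; reported
coefficients and Wald p-values come from an unpenalized logistic refit on
the surviving features. No post-selection correction is applied — the fit
metadata records this caveat — matching the common reporting style of
penalized models with conventional p-values. The default penalty is chosen
by extended BIC (γ = 0.5) along the path: for each distinct support, the
refit deviance plus \(k(\log n + 2\gamma\log p)\). EBIC was preferred over
cross-validated deviance after measurement: with ~17 candidate features and
~800 participant-days, chance features reach |r| ≈ 0.1 and genuinely lower
the CV deviance, so CV (even participant-grouped, with the one-SE rule)
admits a spurious feature in roughly a third of null replicates, while EBIC
keeps the support empty and is fully deterministic. Grouped CV remains
available via `penalty = "cv"`, and any numeric `penalty` fixes λ.

Three families share this machinery, each with night-and-day (.1),
night-only (.2) and day-only (.3) input scopes: **M1** one joint fit over
all participants; **M2** the M1 features refitted per group (effect
stability under a fixed feature set); **M3** selection *and* fit per group.
Night scope means columns recorded while asleep plus sleep duration,
nocturnal awakening and sleep medication; day scope the awake columns plus
awake duration. Tables report features with p < .10 in at least one fit,
mirroring the field's reporting convention.

**Sequential selection and the classifier contract.** A greedy forward
procedure maximising participant-grouped cross-validated AUC (stop when the
improvement is ≤ `tol`, ties broken lexicographically so column order is
irrelevant) is provided for plug-in classifiers. A classifier is any pair
`fit(x, y)` / `predict_probability(model, x)`, deterministic given a seed;
GAMs, SVMs or boosted trees can be plugged in without the package
reimplementing them.

**Evaluation.** `make_balanced_splits()` holds out ⌈20%⌉ of participants
per split (50 splits by default), entirely removed from training; within
the held-out rows the majority class is downsampled without replacement so
every test set is exactly balanced. "Perfect balance" by downsampling rather
than by participant choice preserves subject-wise independence while
guaranteeing equal counts. Accuracy, precision and recall use the 0.5
probability cutoff with high-quality sleep as the positive class; AUC is
pairwise concordance with ties at ½ (checked against an O(n²) oracle).
Aggregates are means over splits.

## The synthetic cohort generator

The generator is first-class, tested code and defines the study conditions:
60 participants (69% in the MS group), 14 days, bed 23:00 ± 30 min, wake
07:00 ± 30 min, daytime HR 75 bpm with a 12 bpm nocturnal dip, nocturnal
HRV gain 1.5, AR(1) beat-to-beat structure (φ = 0.8, daytime marginal SD
30 ms), artifact rate 0.5% per beat, stress habits uniform on 2–6 with
day-to-day SD 1.2, 30% of nights with a reported awakening. Where the
emulated study reports a condition (cohort split, scales, two-week
duration) the default follows it; remaining values are chosen once as
realistic for an adult wearable cohort and documented here.

Responses come from an explicit logistic model: the latent night score is a
linear combination of *normalized* true features (default effects: sleep
duration +0.5, awakening −0.6, stress −0.45, mean SD1 asleep +0.45, motion
asleep −0.4, max SDNN asleep +0.3, plus minimum HR asleep +0.6 in the MS
group only) plus standard logistic noise; the binary label is "latent > 0"
and the 1–5 rating is a monotone discretization of the latent centred near
3.7, so binarizing at the personal mean approximately recovers the labels.
The effect directions mirror the qualitative pattern reported for this
study design.

Two generator levels share this config and response model. The stream level
(`simulate_cohort()`) produces beat-level IBIs (~10⁵ beats per
participant-day), 1 Hz HR and accelerometer, per-second steps, artifact
truth, and diaries; it is the right tool for the signal-processing stages
and is used at small cohort sizes. The feature level
(`simulate_feature_cohort()`) draws the daily feature table directly from
the same marginal structure, making modelling-scale cohorts (hundreds of
participant-days, many replicates) cheap; the recovery and calibration
experiments run there at the full 60 × 14 design.

What the generator does **not** emulate: sleep-stage structure within the
night (one stationary regime per night, an open question in the source
design), true ECG/PPG waveforms, device non-wear gaps, MS disease
progression, or feature correlations beyond the few that are built in.
Passing recovery tests therefore shows the pipeline is correct and
well-calibrated under its stated assumptions — not that real wearable data
meet those assumptions.

## Numerical choices and degenerate inputs

* Population SD in windows; sample SD (n−1) in per-participant
  normalization; both stated on the functions.
* `normalized 0 → low` tie rule; `kept = n_interpolated ≤ 4` boundary;
  strict `<` in the resting rule — all boundary-tested.
* Coefficients are read off the fitted lasso *path* at the chosen λ: a
  single-λ fit is numerically unreliable near the empty-support end of the
  path (it can return a spurious nonzero coefficient).
* A training set in which one class has fewer than two rows falls back to
  an intercept-only fit (chance-level predictions) instead of a spurious
  support.
* Constant response → the Shapiro–Wilk check errors (the statistic is
  undefined); fewer than 3 values → error.
* Exact rank-test enumeration (tie-aware) for combined n ≤ 20, tie-corrected
  normal approximation (no continuity correction) above.
* Perfect separation in a refit is flagged and reported with a warning, not
  hidden.

## Problem sizes used in the checks

The acceptance script and test suite use: 1000 random windows for the
Poincaré oracle; ≥ 200 enumerated rank-test cases (combined n ≤ 8); 200
30-point AUC sets; 20 replicate cohorts at 60 × 14 (feature level) for sign,
magnitude and group-specific recovery and for null calibration; 20 synthetic
nights (stream level) for segmentation; two-participant stream cohorts at 2%
artifact rate for the detector. These sizes keep every experiment
reproducible in minutes on one core while leaving the Monte-Carlo error well
below the asserted margins.

## Known limitations

* The evaluation AUC of a model trained on ~48 participants sits a few
  hundredths below the generator's Bayes ceiling (the AUC of the noise-free
  latent score); this finite-sample gap is expected and the tests assert the
  achievable band rather than the ceiling itself.
* p-values after L1 selection are conventional refit p-values without
  post-selection adjustment; treat them as descriptive, as in the reporting
  convention they mirror.
* The automated segmenter is a measurable stand-in for manual labelling; on
  real data its thresholds (`activity_rel`, `hr_rel`, smoothing, bridging)
  may need retuning, which is why all of them are arguments.
* Normative HRV tables are user-supplied; the bundled ones are synthetic.
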