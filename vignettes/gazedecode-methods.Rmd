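---
title: "Auditing gaze confounds in orientation decoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing gaze confounds in orientation decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazedecode)
```

## The problem

Decoding analyses read stimulus identity out of multivariate recordings.
Under attempted fixation the eyes still move — drift, microsaccades,
tremor, and occasional frank saccades — and because early visual cortex is
retinotopic, any eye movement that covaries with the stimulus can masquerade
as neural stimulus information. `gazedecode` asks the diagnostic question
directly of the eye tracker: *can stimulus orientation be decoded from gaze
alone?* If yes, neural decoding results from the same session inherit an
alternative explanation.

The pipeline treats the gaze recording exactly like a decoding dataset:
preprocess, summarize per trial, cross-validate a classifier, and test
significance against a label-permutation null. Everything downstream of the
raw samples — filtering, epoching, feature definitions, classifier,
inference — is specified here so the audit is reproducible.

## Session design

A session is 12 runs; each run presents the 8 grating orientations
(0–157.5° in 22.5° steps) twice in random order: 16 trials of 7 s at a 2 Hz
on/off presentation (250 ms on, 250 ms off), 1 s inter-trial interval, and
8 s of fixation-only at both ends of the run. Binocular gaze and pupil size
are sampled at 1000 Hz. In the *active* session 12.5% of trials are task
trials — three per orientation, allocated to runs at random — in which one
"on" period between 1 and 6 s into the trial shows the grating perturbed by
10° (either direction); participants respond with a button press. The
*passive* session is identical without the task. Task trials are excluded
from decoding because the perturbation itself may evoke eye movements,
leaving 168 of 192 active-session trials.

`make_design()` validates all of this (orientation spacing, the
trials-per-run/orientations invariant, the task-fraction arithmetic) and
carries the task-trial allocation plan.

## Preprocessing

The chain runs per run, in fixed order:

1. **Blink repair** (`repair_blinks`): missing samples are replaced by the
   channel's median over the run's valid samples — i.e. by the fixation
   point for gaze channels. The mask is kept for provenance.
2. **Low-pass** (`lowpass`): Butterworth, order 5, cutoff 100 Hz, applied
   forward and backward so the net phase is zero. Zero phase matters because
   saccade *timing* feeds the velocity-based analyses; a causal filter would
   delay every event by the group delay. The pass is seeded with the
   steady-state filter state for the first sample (the classic
   `lfilter_zi` construction) plus odd-reflection padding, so edges carry no
   start-up transient. The effective magnitude response is the square of the
   single-pass response; DC is preserved exactly.
3. **Downsampling** (`downsample`): cubic-spline interpolation onto the
   exact 256 Hz grid. The 100 Hz low-pass is the anti-alias stage; on a
   signal band-limited to 0.2 of the source Nyquist frequency, spline
   interpolation is exact to < 0.05% even at the cutoff (measured against
   analytic sinusoids), which is why no separate polyphase FIR stage is
   used. 7 s of signal becomes exactly 1792 samples.
4. **Epoching** (`epoch_trials`): one epoch per `trial_onset` event, locked
   to the first stimulus presentation, 1792 samples, labelled with
   orientation, task flag, and run.
5. **Run-median centering** (`center_runs`): per run and channel, the median
   over all of the run's epoch samples is subtracted. This expresses gaze
   relative to the fixation point and removes slow per-run offsets
   (head-position drift, calibration bias). Pupil channels are centred the
   same way. The median is computed over the epochs' samples (not the
   inter-trial samples), since epochs are what every downstream stage
   consumes.

Re-running the chain on its own output changes nothing except the filter
(squaring a low-pass response is not idempotent; this is inherent, not a
bug).

## Features and decoding

Each trial is summarized by the mean and standard deviation of the six
channels (x/y per eye, pupil per eye): 12 features. The SD uses the
population (divide-by-*n*) convention — immaterial at n = 1792 but fixed for
bit-reproducibility. "Eye-movement amplitude" is defined as the mean over
samples of the binocular-average radial distance from fixation
(`trial_amplitude`), averaged over trials for a participant-level value;
the quantity is not standardized in the literature, so the definition is
stated here and kept configurable by composing the exported pieces.

Decoding is 10-fold stratified cross-validation. Per fold, features are
robust-scaled by the training rows' median and IQR (validation rows never
touch the scaler), then a linear maximum-margin classifier is trained:
hinge loss, C = 0.1, one-vs-rest. The solver is a dual coordinate-descent
routine (the standard large-scale linear-SVM algorithm) compiled via Rcpp,
with the bias handled as an augmented regularized feature, a deterministic
internal shuffle, and the conventional dual stopping tolerance of 0.1. The
one-vs-rest scheme is stated explicitly because libsvm-based R wrappers
default to one-vs-one; tests verify the binary solution against `e1071`
(the same QP up to bias regularization) and multiclass behaviour on
separable data.

If any class has fewer trials than folds, the result is an explicit
insufficient-data sentinel, not a number. This matters for the filter
sweeps, where aggressive thresholds can leave too few trials to decode; a
sentinel participant is flagged and excluded from paired comparisons rather
than being assigned a fake accuracy.

**Permutation inference.** The null distribution is built by rerunning the
entire decoding pipeline (stratification, scaling, training) on uniformly
permuted labels, 1000 times by default. Two summaries are reported: the
add-one p-value `(1 + #{null ≥ observed}) / (1 + n_perm)`, and a
significance flag defined as *observed strictly above the empirical 95th
percentile of the null* — the flag is the operative criterion, the p-value
is informative. With 200 permutations (the calibration scale used in the
tests) the rejection probability under exchangeability is 10/201 ≈ 5%.

## Microsaccade detection and trial filtering

Velocity is estimated with the 5-point moving-window formula
`v[n] = (p[n+2] + p[n+1] − p[n−1] − p[n−2]) / (6Δt)` per component and eye
(exact for linear motion, noise-suppressing otherwise), on the preprocessed
256 Hz data — the same signal the decoder consumes. Microsaccades are
samples outside the ellipse with semi-axes λσ per component, where σ is the
median-based spread `sqrt(median(v²) − median(v)²)` and λ = 6; runs of at
least 6 ms become events; events are kept when detected in both eyes with
≥ 1 sample of temporal overlap (the binocular criterion). Amplitude is the
onset-to-offset displacement. λ and the minimum duration are the cited
methodology's standard values.

Trial filters implement the two fixation-control counterfactuals: remove a
trial if the binocular-average gaze ever exceeds a distance threshold (a
circle around fixation), or if the binocular speed ever exceeds a velocity
threshold (a saccade was made). `threshold_sweep()` runs a grid of
thresholds (defaults: 0.25–4° and 10–100°/s, plus an unfiltered "none"
condition) over a cohort, decodes the kept trials per participant, and
compares sessions per threshold with a paired signed-rank test,
Bonferroni-corrected across the swept conditions.

## The synthetic-session generator

The generator exists so the pipeline can be exercised, calibrated, and
power-checked end to end. It emulates, per run, a 143 s sample stream at
1000 Hz with:

- **Drift**: a mean-reverting (Ornstein–Uhlenbeck) walk, τ = 0.7 s,
  innovation 0.2 °/√s → ≈ 0.12° stationary scatter, bounded near fixation.
- **Microsaccades**: Poisson events at 1.2/s, amplitudes uniform on
  0.05–0.25°, raised-cosine velocity profiles with a linear main sequence
  (v_peak = 20 + 60·amplitude °/s). Directions are uniform until the
  accumulated offset exceeds 0.15°, after which events re-center gaze —
  fixation is actively maintained, and the resulting ≈ 0.21° mean radial
  amplitude matches what steady fixators produce.
- **Blinks**: Poisson at 3/min, 150 ms, recorded as missing-sample spans;
  spans are never allowed to cover a trial-onset sample so epoching stays
  well defined.
- **Pupil**: a slow common OU component (τ = 5 s, ~1%) plus white per-eye
  noise around an arbitrary-unit baseline.
- **Vergence noise**: small independent per-eye OU components (~0.03°), so
  the eyes are strongly but not perfectly correlated.

**Orientation-dependent bias** is what the package is for, so its shape is
the generator's most deliberate choice. A fraction of trials
(`bias_trial_prob`, default 0.3) are "tracked": they contain saccadic
excursions (Poisson, 1/s within the trial) along the trial's orientation
axis (θ mod 180°; or the orthogonal axis in `orthogonal_axis` mode),
launched at stimulus-on onsets: an outward main-sequence saccade to
`bias_amplitude` degrees, a 250 ms hold, and a return saccade. Each session
draws a preferred direction per orientation (which end of the axis), and
excursions follow it with probability 0.9 — biased observers show
direction-consistent, asymmetric per-orientation gaze lobes, and a fully
sign-symmetric construction would make θ and 180°−θ indistinguishable to a
mean/SD feature set (no x–y covariance feature exists), capping decodability
near chance regardless of amplitude. The saccadic (fast) excursion shape is
equally deliberate: it makes biased trials detectable by *both* the
distance filter and the velocity filter, as a confound caused by real
saccades would be. With `mode = "none"` the orientation labels are
independent of the traces by construction.

At amplitude 0 the excursion generator still runs (injecting nothing), so
sessions differing only in `bias_amplitude` share every other random draw.
Amplitude sweeps are therefore paired comparisons — common random numbers —
which is what makes a 10-seed monotonicity check informative. Even so, the
per-step paired differences at the smallest amplitudes are of the same
order as their Monte-Carlo standard errors, so the monotonicity checks are
phrased at the resolution the sample supports: no step may *decrease* by
more than twice its standard error, the within-seed amplitude–accuracy
trend must be clearly positive, and the full-range rise must be large.

What the generator does **not** emulate: tremor as a distinct component,
saccadic suppression, pupil foreshortening artifacts, calibration drift,
session-level fatigue, or any participant strategy beyond the single
tracked-trial mechanism. Passing tests on synthetic cohorts therefore show
that the pipeline is correct and calibrated, not that real data are free of
other structure.

## Group statistics

`wilcoxon_paired` discards zero differences, reports min(T⁺, T⁻), and
switches estimator by regime: the closed-form signed-rank null for tie-free
n ≤ 25, exhaustive 2ⁿ sign enumeration (average ranks) for tied n ≤ 14, and
the continuity- and tie-corrected normal approximation otherwise.
`wilcoxon_vs_chance` is the same test against a constant (12.5% for 8
classes). `spearman_ci` uses average ranks, the t-approximation for the
p-value, and a Fisher-z interval with SE 1/√(n−3) — an approximation whose
coverage is nominal for rank correlations; it is reported as such and not
treated as exact. `bonferroni` flags p < α/m. The session-order check pairs
active-first with passive-first participants' difference scores.

## Problem sizes and seeds

The test suite runs reduced designs (2–6 runs, 4–8 orientations) for unit
checks and full-scale sessions where calibration is the point: the
acceptance tests use a 120-participant bias-free cohort at 200 permutations
for the type-I calibration, 10 common-random-number seeds per amplitude for
the bias sweep, and 6 sessions for the filter counterfactual — sizes chosen
to estimate each rate with useful precision while keeping a full run in the
minutes range on one core. All randomness is seeded; `run_study()` derives
per-participant, per-stage seeds from one master seed so cohorts are
reproducible while participants stay independent.

## Known limitations

- The 12-feature set carries no x–y covariance, so axis pairs symmetric
  about the cardinal directions are genuinely harder; this mirrors the
  audited method rather than improving on it.
- The Fisher-z CI for Spearman's ρ is approximate.
- The permutation test permutes labels freely, while the design balances
  labels within runs; the calibration cohort exists precisely to verify that
  this mismatch does not inflate the type-I rate at the study's scale.
- Real eye-tracker exports must be converted to the documented tabular
  format (and pixels to degrees via `pixels_to_degrees`); vendor formats are
  out of scope.
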