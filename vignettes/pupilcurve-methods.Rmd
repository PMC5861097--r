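---
title: "Task-evoked pupillometry with pupilcurve: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-evoked pupillometry with pupilcurve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pupilcurve` analyses task-evoked pupillary responses (TEPRs) recorded
while participants make perceptual decisions about emotional stimuli —
the canonical case being nonverbal vocalizations (laughs, cries,
screams) judged for emotional valence under isoluminant conditions. The
pupil dilates slowly during stimulus processing, peaks shortly after the
decision is expressed (a keypress), and returns to baseline. The package
covers the full path from raw eye-tracker samples to inference: a
synthetic-data generator with a known effect structure, blink repair and
smoothing, baseline correction, per-trial curve statistics, event-locked
aggregation, and mixed-effects regression whose coefficients are scaled
for direct comparison across predictors.

This vignette documents the models, the tunable parameters, the design
choices made where several defensible options existed, and the known
limitations. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` compute themselves.

## The generative model

Every stage downstream of data ingestion is testable because the
generator produces datasets whose ground truth is known. One trial's
pupil trace at the native rate (default 120 Hz) is

$$
d(t) \;=\; B \;+\; A \cdot s(t) \;+\; \varepsilon(t),
$$

where

* $B$ is the pre-trial baseline diameter: the participant's resting
  diameter $R$ (drawn once per participant, $\mathcal N(5.2, 0.5^2)$ mm)
  times a per-trial ratio $\mathcal N(0.99, 0.09^2)$. The ratio's
  moments reproduce the empirical regime in which pre-trial baselines
  scatter tightly around the resting level.
* $s(t)$ is the normalised response shape: a boxcar of sustained
  attention spanning sound onset to the response keypress, convolved
  with the Erlang-family pupil kernel
  $h(t) = (t/t_{\max})^{n}\, e^{\,n(1 - t/t_{\max})}$ and divided by its
  maximum over the trial's own sample grid. The grid-max normalisation
  is deliberate: it makes the noiseless sampled peak equal $A$ exactly,
  so zero-noise feature extraction and regression recover the configured
  coefficients to machine precision — a sharp end-to-end correctness
  check that a continuous-time normalisation would blur by a
  discretisation term.
* $A$ is the evoked amplitude, a linear combination of the scaled
  covariates (valence intensity /50, confidence /100, duration and
  response time over their observed ranges) with the configured effect
  sizes, plus a participant intercept and trial-level noise.
* $\varepsilon(t)$ is slow physiological noise — AR(1) with stationary
  SD `noise_sd` (default 0.03 mm, coefficient 0.96 at the 120 Hz step,
  time constant roughly 0.2 s) — plus white measurement noise
  (`measurement_noise_sd`, default 0.02 mm). These defaults represent a
  research-grade video tracker after source filtering; they were chosen
  once, on the grounds below, and are configurable.

Blinks arrive as a Poisson process (default 12/min) with lognormal
durations (median 0.15 s) and are masked as missing; a small per-trial
probability of a long tracking dropout (2–6 s) and of a gaze-displacement
episode gives the validation stage realistic work to do, with total
exclusions landing in the low single-digit percent.

### Why the baseline effect is state-dependent

Peak diameter mechanically contains the baseline: adding 1 mm of
baseline adds 1 mm of peak, which on the scaled metric (baseline range
3.0–7.0 mm) is a coefficient of 4.0. An empirical baseline coefficient
*below* 4.0 therefore means the evoked response shrinks as baseline
rises — a ceiling effect. The generator implements that attenuation on
the pre-trial *deviation from the participant's own resting diameter*,
not on absolute diameter. Two reasons. Physiologically, the ceiling is a
state phenomenon: a pupil dilated above its own resting level has less
headroom, whereas an anatomically large pupil does not respond less.
Statistically, loading the attenuation on absolute diameter forces
negative evoked amplitudes for large-pupil participants; a maximum-based
peak extractor then floors those trials at baseline and biases the
recovered baseline coefficient upward by an amount that can exceed its
own confidence interval. With the state-dependent loading, the
amplitude's baseline term is `effect_sizes$baseline` minus the 4.0 mm
passthrough, so a mixed regression of peak diameter on scaled pre-trial
baseline recovers `effect_sizes$baseline` itself — the number the
configuration states.

### Kernel calibration and the response-to-peak lag

The kernel's time-to-peak is not set directly; it is calibrated so that
the mean noiseless response-to-peak lag over a representative spread of
boxcar lengths equals `peak_lag_mean` (default 0.37 s) plus a 0.28 s
wander compensation. Two effects make the calibration nontrivial. For
boxcars longer than the kernel support the convolution saturates into a
flat plateau and its argmax slides *before* the response; averaging over
realistic response times accounts for that. And because the response top
is broad, even small noise breaks near-ties and pulls the realized
argmax backward by roughly 0.3 s at the default noise level; the
compensation restores a realized trial-level mean lag near the target.
The lag's trial-to-trial spread in the generator (~0.5 s SD) is
substantially tighter than in real recordings (SDs above 1 s are
common); see Limitations.

### Foreperiod and stimulus set

Stimulus onset follows a non-ageing foreperiod: 5 s plus an exponential
delay with constant hazard (default 0.3/s), right-truncated so the total
never exceeds 11 s. The inverse-CDF sampler is tested against the
closed-form truncated-exponential distribution (Kolmogorov–Smirnov
distance below 0.01 at $10^5$ draws). The 72-sound stimulus set emulates
an eight-category corpus of nonverbal vocalizations with
category-typical durations (clamped to 0.5–6 s), valences on the
−50..+50 scale, and an ambiguity score that drives simulated confidence
(decreasing) and response times (increasing, also increasing with sound
duration).

## Preprocessing

The cleaning chain per trial is: detect artifact intervals, repair by
cubic spline, Savitzky–Golay smoothing, decimation to 30 Hz. Choices and
their reasons:

* **Artifact signature.** Missing or zero samples, diameters outside
  (0, 12) mm, and between-sample jumps larger than 1 mm (device
  artifacts around blinks). Each run is padded by 50 ms per side and
  overlapping intervals merge. All thresholds are arguments.
* **Spline anchors are spaced, not adjacent.** The repair spline (FMM
  end conditions; exact on locally cubic signal) uses four anchors per
  side spaced 50 ms apart. Anchors taken from adjacent samples estimate
  the end derivative over a single 8 ms step, amplifying measurement
  noise by the inverse step and producing overshoot across the gap —
  which a maximum-based peak extractor then harvests as spuriously
  inflated peaks. Spacing the anchors removes that inflation without
  affecting polynomial exactness.
* **Smoothing precedes decimation.** The window-21, order-3
  Savitzky–Golay filter reproduces cubic signal exactly while acting as
  the anti-aliasing step before keeping every 4th sample. Decimation
  (not bin averaging) is used because the smoothing step has already
  done the averaging work.
* **Validity.** The missing fraction is computed over the full trial
  window *before* interpolation; a trial is invalid when it strictly
  exceeds 20% or when gaze left fixation for more than 100 ms (deviation
  above 2° when a gaze-deviation column is present, otherwise the
  gaze-valid flag). Trials are excluded wholesale, not repaired into the
  analysis.

## Curve statistics

Per trial, after preprocessing:

* **Pre-trial baseline**: mean diameter over the 1.3 s before sound
  onset (39 samples at 30 Hz). **Resting baseline**: mean of the
  cleaned resting recording; the recording length is a parameter
  (default 45 s) because protocols differ on 45 s vs 60 s, and the
  estimator needs at least 30 s of valid samples either way.
* **Peak dilation and peak time**: maximum diameter from sound onset to
  the recording end (response + 4.5 s), earliest sample on ties; time
  reported relative to onset.
* **Dilation rate**: peak height over peak latency. The numerator is
  baseline-subtracted by default — a ratio of *absolute* diameter to
  time has no slope interpretation — but the absolute-numerator variant
  is available behind `baseline_subtract = FALSE` since published
  descriptions of this statistic are ambiguous on the point. Trials
  peaking before 0.25 s are flagged (`rate_excluded`) because
  small-denominator ratios are outlier-prone; they are dropped only from
  the dilation-rate model, not globally.
* **Contraction rate**: diameter drop over the 2 s after the peak,
  divided by 2; positive means shrinking, so "contracted faster" maps to
  larger values. Flagged unavailable when under 2 s of post-peak data
  exists (recording length varies with response time).
* **Response-to-peak lag**: peak time minus response time, the quantity
  that ties the pupil curve to the decision.

The "baseline" predictor used in the models is the pre-trial diameter in
mm (scaled over 3.0–7.0 mm), not the ratio to resting baseline: the
printed 3.0–7.0 mm range identifies it as a diameter, and the ratio
remains available as a grouping variable for aggregate curves.

## Aggregation

Trials are converted to percent change relative to their own pre-trial
baseline, time-locked to sound onset or to the response keypress
(nearest-sample snapping onto the common 30 Hz grid, error at most half
a sample period), and averaged per group and timepoint with the SEM over
contributing trials. Ragged trial lengths are handled by aggregating
whichever trials have data at a timepoint, with the per-timepoint n
reported; nothing is truncated to the shortest trial. Default groupings:
valence sign with cuts at ±10 (configurable; the neutral band is a
convention), valence-intensity and baseline-ratio tertiles (quantile
bins, since published figures do not state their edges).

## Inference

* **Scaled coefficients.** Every numeric predictor is mapped to [0, 1]
  over its stated range, so a coefficient reads "expected change in the
  outcome when this predictor moves across its full observed range". A
  consequence worth stating: *doubling* a stated range *doubles* the
  coefficient (the full-range change is twice as large), and the
  likelihood-ratio statistic is invariant to any affine rescaling.
* **Estimation.** Gaussian linear mixed models with a participant random
  intercept, fitted by maximum likelihood (lme4). Significance per
  predictor comes from likelihood-ratio tests of nested ML fits;
  interval estimates come from the profile likelihood. This
  frequentist pairing — LRT for significance, profile intervals for
  uncertainty — is the package's interval path; profile intervals agree
  closely with posterior intervals under weak priors at these sample
  sizes, and the implementation stays sampler-free. Singular
  random-effect fits are flagged on the result object.
* **Rating model.** Perceived and induced valence are modelled jointly
  on the open unit interval with a beta response (glmmTMB), an
  emotion-by-rating-type interaction, and crossed random intercepts for
  participant and stimulus. Ratings are compressed off the boundary with
  $y' = (y(n-1) + 0.5)/n$, the standard transform for beta regression
  with attainable endpoints. Degenerate designs (a single emotion level)
  drop the interaction rather than fail.
* **Surface.** The decision-locked percent-change samples are fitted
  with a tensor-product smooth `te(time, valence)` plus a linear
  pre-trial-baseline term (mgcv, REML). A tensor product is used rather
  than an isotropic bivariate smooth because time (seconds) and valence
  (−50..50) are on incommensurable scales. A constant response
  short-circuits to the flat surface, and a near-constant baseline term
  is dropped as collinear with the intercept.

## Numerical conventions

Ties in peak extraction resolve to the earliest sample. Event snapping
uses nearest-sample assignment. Blink intervals are half-open on the
time axis. Gaps touching a trace edge with fewer than two anchors per
side stay missing and produce a warning rather than an extrapolated
repair. The decimation factor must be an integer; other ratios are an
error, not a resample.

## Problem sizes in the test suite

The unit suite exercises the stages on small synthetic studies (two to
ten participants, tens of trials) where oracle comparisons are exact or
cheap; the acceptance suite runs one full 33-participant, 72-trial study
through the complete pipeline and checks that the peak-dilation model's
profile intervals cover the generative effect sizes, that the
permutation type-I error of the LRT sits near its nominal level over 500
replicates, and that the structural outputs (coefficient table, locked
curves, surface) have the documented shape. These sizes are the
package's own choices: large enough for the distributional checks to be
sharp, small enough to run routinely.

## Limitations

* The generator is cleaner than real data. Its response-to-peak lag SD
  (~0.5 s) understates the variability of real recordings, its noise is
  stationary, and it contains no gaze-angle foreshortening, no luminance
  responses, no slow drift in arousal, and no post-blink recovery
  artifacts. Passing recovery tests therefore demonstrates correctness
  of the pipeline's computations under the stated model, not robustness
  to every failure mode of real eye-tracking data.
* Maximum-based peak extraction is upward-biased under noise, and the
  bias grows with the search-window length. The preprocessing choices
  (spaced spline anchors, smoothing before decimation) were made to keep
  that bias small relative to the coefficient intervals, but the
  response-time coefficient remains the most exposed to it.
* The beta rating model reports fitted central tendencies with Wald
  intervals on the response scale; with heavily imbalanced designs,
  profile or bootstrap intervals would be preferable.
* The 20% missing-data rule, the ±10 valence cuts, and tertile bin edges
  are conventions; all are parameters, and results near those boundaries
  deserve sensitivity checks.
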