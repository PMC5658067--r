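---
title: "Methods: slow calcium wave detection and event-related BOLD analysis"
author: "slowbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow calcium wave detection and event-related BOLD analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowbold)
```

# Scope

`slowbold` implements an analysis chain for paired optical and fMRI
recordings under anesthesia-induced slow-wave activity: fiber-photometry
traces carrying stereotyped population calcium waves (up states) separated
by quiescence (down states), and simultaneous whole-brain BOLD EPI at
TR = 1 s.  The chain comprises

1. calcium preprocessing (block-average downsampling 2 kHz to 1 kHz,
   zero-phase low-pass, spline baseline correction over 2500-sample
   windows),
2. slow-wave segmentation with an exponential moving average (EMA) filter
   and histogram-derived thresholds, plus post-processing rules and
   per-wave quantification (rise time, duration, amplitude),
3. model-free finite impulse response (FIR) extraction of the hemodynamic
   response (HR) to wave onsets, gamma-variate fitting, and quantification
   as time-to-peak (TTP), normalized peak amplitude (dSA) and half-maximum
   duration (HMD),
4. event-related GLM activation mapping with AR(1) prewhitening,
   discrete-cosine high-pass, Gaussian smoothing and Bonferroni
   family-wise error (FWE) control,
5. seed-based and calcium-informed correlation mapping with cluster-extent
   filtering, and specificity controls (time-mirrored and session-swapped
   event regressors),
6. a synthetic-data generator producing paired sessions with known ground
   truth, against which every stage is validated.

# The synthetic generator

No public recordings of this kind exist, so all validation rests on
synthetic sessions whose parameters are the published summary statistics
of the in-vivo data.

## Calcium waves

A wave is modelled as a linear rise to peak over `2 * rise_time` (so the
onset-to-half-maximum interval equals `rise_time` by construction),
a plateau at peak amplitude, and an exponential decay.  The plateau
represents the sustained depolarized up state; the decay constant
(550 ms) is indicator-limited, OGB-1-like.  The plateau duration is
derived so that the planted half-maximum duration
(`rise + plateau + tau * log(2)`) equals the target mean duration.  A pure
rise-plus-exponential wave with a 1356 ms half-maximum duration would need
tau near 1.9 s; its multi-second tails would overlap successive waves at
10.9 events/min and defeat any windowed baseline estimator, and such tails
are not seen in the recordings this emulates, which motivated the plateau
form.

Presets:

```{r presets}
str(calcium_preset("ogb1")[c("event_rate_per_min", "rise_time_ms",
                             "plateau_ms", "decay_tau_ms",
                             "amplitude_dff", "refractory_s")])
```

* OGB-1: rise 72 ms; GCaMP6f: rise 163 ms (slower calmodulin kinetics);
  both share mean half-maximum duration 1356 ms and amplitude
  2.6 delta-f/f at a mean rate of 10.9 events/min.
* Inter-onset intervals are exponential with a hard refractory period.
  The refractory default is 2.5 s: the waveform stays above the
  termination threshold for about 1.6 s and the 100 ms merge rule needs
  clearance, so a shorter refractory would fuse consecutive waves into
  single suprathreshold segments, which the generator is designed to
  avoid (waves in these recordings do not ride on each other's
  suprathreshold phase).
* Per-wave parameters are log-normal around their means (rise CV 0.15,
  plateau CV 0.3, amplitude CV 0.05 by default).  Real waves are variable;
  a zero-variance plant would also make standard-error-based recovery
  checks degenerate.  In the rare case that a drawn duration would overlap
  the next onset it is clipped to the available gap.
* Baseline drift is a slow sinusoid (0.1 delta-f/f, 300 s period) and
  noise is white Gaussian (SD 0.05 delta-f/f).  Silent-period baseline
  statistics are not published; both are free parameters.

## BOLD sessions

Cortical voxels (a contiguous slab of upper slices) carry the event
vector convolved with a gamma-variate HR; other voxels carry drift and
noise only.  The planted response is parameterized by its descriptive
shape — TTP 6.5 s, peak 0.17% signal change, HMD 6.8 s, onset latency
0.7 s — from which `gamma_variate_params_from_shape()` solves the
gamma-variate parameters.  Design choices:

* **Onset impulses, not duration boxcars.**  The published HR shape is
  the measured response to a slow wave, so the generator plants it as the
  response to each wave onset.  Convolving additionally with multi-second
  duration boxcars would widen and delay the planted response, making the
  printed TTP unrecoverable by construction.  `stimulus = "boxcar"` is
  available.
* **Amplitude hotspot.**  Response amplitude falls off smoothly in-plane
  (Gaussian, sigma 6 voxels) from a most-responsive location carrying
  exactly `response_amplitude_pct`, to a floor of 0.85 of it.  With
  spatially identical cortical voxels, "most active voxel" selection is
  decided purely by noise and inflates extracted amplitudes by roughly
  8–10% — the classic circular-selection bias; a hotspot is also what a
  somatosensory activation focus looks like.  `amplitude_profile =
  "uniform"` is available for exactness tests.
* **Noise** is AR(1) Gaussian (coefficient 0.3, matching the AR(1) model
  the analysis assumes) with marginal SD 0.65% of the mean-100 baseline
  (temporal SNR about 150, attainable with a surface coil over cortex at
  high field).  This level was fixed by a power analysis: with the
  planted 0.17% amplitude and 20-min sessions, family-wise-corrected
  recovery of essentially the whole cortical slab requires noise below
  about 0.7%, while the specificity controls (below) become increasingly
  anti-conservative as noise falls further.
* Baseline mean is exactly 100, so percent signal change is well defined;
  a noiseless isolated event peaks at exactly `response_amplitude_pct` at
  the hotspot centre.

# Detection

The preprocessed 1 kHz trace is EMA-filtered (25 ms window,
`y_t = alpha x_t + (1 - alpha) y_{t-1}`, `alpha = 2/(N+1)`).  The
reference amplitude is the 99.9th percentile of the filtered amplitude
histogram — a trimmed maximum honouring the percent-of-maximum convention
while ignoring isolated artifact samples.  Onsets are upward crossings of
70% of the reference; terminations are downward crossings of 50% of the
onset threshold.  Post-processing applies, in order: merge gaps strictly
below 100 ms; discard waves strictly shorter than 600 ms; discard waves
whose peak does not reach the 90th percentile of the reference amplitude
histogram.

For the third rule the histogram convention matters.  Taking the 90th
percentile of *all* samples (or of suprathreshold samples) places the
criterion inside the peak-amplitude distribution whenever waves occupy an
appreciable fraction of the recording — at 10.9 events/min about half the
true waves would be discarded, which is clearly not the rule's purpose.
The default reference is therefore the sub-threshold (noise and baseline)
amplitude distribution, making the rule a noise-floor filter;
`intensity_ref = "all_samples"` exposes the stricter reading.

Because the EMA is tuned for onsets, terminations are refined against the
noise level: each termination is extended to the last sample above
baseline + 2 noise SD before the signal stays below that level for at
least 50 ms, clamped at the next onset.  The noise SD is estimated from
the lower tail of the amplitude distribution (5th–25th percentile range),
which is insensitive to the positive-going waves.

The 70% threshold fraction can be recalibrated against the paired BOLD
data (`calibrate_threshold()`): detection is repeated over candidate
fractions, each followed by a GLM, and the fraction at the inflection
(maximum discrete second difference) of the suprathreshold-voxel-count
curve is returned, with 0.70 as the guarded default.

## Per-wave quantification

Rise time is the interval from wave onset to the half-maximum crossing.
The detected (threshold-crossing) onset lies well above the true onset,
so the onset is recovered by extrapolating the 25–75% rising flank down
to the local baseline — exact for a linear rise and unbiased under
noise.  The local baseline is a 200 ms window ending 300 ms before the
detected onset, clear of the crossing lag.  Duration is the first-to-last
time above 50% of peak; the falling crossing must be sustained (50% for
at least 100 ms) so that noise bounces and the next wave's flank are not
mistaken for it.  Amplitude is the mean of all samples within two noise
SDs of the within-event maximum: for plateaued waves this is an unbiased
peak estimate, where the raw maximum would carry the positive bias of the
noise extremum.

Quantification runs use a permissive onset threshold
(`onset_threshold_frac = 0.4`).  At the mapping default of 0.7 the
threshold sits near the centre of the peak-amplitude distribution when
wave-to-wave variability is wide (CV 0.2), censoring small waves and
biasing the recovered mean amplitude upward; morphology estimation needs
an unbiased sample, whereas event-timing mapping needs specificity.

# Hemodynamic response estimation

The slow-wave vector (events binarized to volumes by the half-open
overlap convention) anchors an FIR basis of 40 one-second bins spanning
-20 s to +20 s around each onset; per-voxel ordinary least squares on
this design (plus intercept) yields 40 beta maps in percent signal change
(betas scaled by the voxel temporal mean).  The omnibus F-test over all
40 bins (the pre-onset bins included) thresholded at p < 0.05 defines the
activation map from which the 10 highest-F voxels in the most active
slice and its two neighbours (30 voxels) are taken for timecourse
extraction; an exclusion mask (e.g. sinus vein) is honoured and ties
break by ascending index.  The 30 beta series are averaged and the mean
of the 5 s pre-onset bins subtracted.

Two distinct uses of the extracted curve:

* **As a convolution kernel** (`assemble_leave_n_out_hrf()`): curves from
  the *other* sessions are averaged, truncated to 0–15 s (back at
  baseline) and unit-peak normalized, avoiding circular analysis.  Any
  selection-induced amplitude bias cancels in the normalization.
* **For quantification** (TTP, dSA, HMD): the response is fitted by a
  unit-peak gamma variate,
  `y(t) = amp ((t - t0)/(alpha beta))^alpha exp(alpha - (t - t0)/beta)`,
  by multi-start Levenberg–Marquardt least squares, and the quantities
  are evaluated on the fit (TTP = `t0 + alpha*beta`; HMD solved on the
  continuous curve).  Quantification is done on ROI-averaged responses
  (a fixed anatomical ROI over the activation focus — 5 x 5 in-plane
  through the cortical slab thickness, as one would draw on a mean
  functional image across slices) rather than on the F-selected voxels: selection among statistically near-tied voxels inflates the
  extracted amplitude multiplicatively, and an a-priori ROI is immune.
  A centred moving-average smoother (`smooth_n`, default off) is
  available for noisy single-voxel curves; applied to a well-averaged
  curve sampled at 1 s it flattens the peak by about 10%, so the fit
  defaults to the unsmoothed curve.

The canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6) is
provided for the comparison analysis.

# Event-related GLM

Preprocessing discards the first 5 volumes, smooths with a 0.5 mm FWHM
Gaussian (converted to voxels via the header geometry, edge-renormalized)
and removes drift with a discrete-cosine basis up to 1/128 Hz.  The same
cosine basis is projected out of every design fitted to the session
(Frisch–Waugh), and the residual degrees of freedom are reduced
accordingly — filtering only the data would bias betas toward zero.

Event regressors are duration boxcars (or onset impulses) convolved with
the chosen HR kernel and mean-centred.  Serial correlation is handled by
a single pooled AR(1) coefficient estimated from the lag-1
autocorrelation of OLS residuals over in-mask voxels, followed by
Cochrane–Orcutt prewhitening and refitting.  F-tests use the
extra-sum-of-squares ratio; t-maps are thresholded at p < 0.05 with
Bonferroni FWE control (random-field theory is out of scope; Bonferroni
is conservative under smoothing).  ROI comparisons test normality per
sample (Lilliefors) and use Student's t when tenable, otherwise the
Wilcoxon rank-sum test.

# Correlation analyses and controls

Seed-based maps correlate a seed-mean timecourse with every target voxel
(threshold r = 0.5; clusters of at least 300 voxels, 26-connectivity).
The calcium-informed analysis baseline-corrects each voxel with a 100 s
rolling window, computes per-voxel event-locked average responses on the
0–20 s grid, correlates them with the ROI-mean reference response
(threshold r = 0.8, clusters below 70 voxels removed) and derives a TTP
map (onset to maximum of the event-locked response) over the surviving
region.  Event-locked correlation is used rather than full-timecourse
correlation because the reference is itself an event-locked response;
both interpretations of the underlying procedure are defensible and the
event-locked one is exposed.

Specificity controls rerun the GLM with time-mirrored events
(`(onset, d) -> (T - onset - d, d)`, preserving counts, durations and
interval statistics) and with event arrays swapped in from another
session.  On synthetic coupled sessions the true regressor recovers over
95% of the planted cortical slab while control regressors stay near
chance.

**Known limitation.**  Control analyses on coupled data are mildly
anti-conservative: every cortical voxel shares the same realization of
the true event-locked signal, whose chance correlation with a control
regressor (both are kernel-filtered point processes) shifts all cortical
t-values coherently.  At the study conditions, roughly 1 in 7 control
analyses shows a single FWE-suprathreshold voxel against the nominal 1
in 20.  The effect scales with per-voxel CNR and cannot be removed by
whitening; at in-vivo noise levels it is negligible, and it is the price
of generator conditions strong enough for near-complete true-positive
recovery.

# Numerical choices

* Zero-phase filtering uses odd-reflection padding so constants and
  linear trends pass unchanged.
* The rolling baseline estimator is two-pass: a 10th-percentile pass
  flags samples more than 5 robust SDs above the provisional baseline;
  the second pass takes the per-window median of unflagged samples
  (unbiased under symmetric noise), windows with under 20% usable samples
  contribute no knot, and a natural spline interpolates knots across the
  trace.
* Gamma-variate fitting multi-starts over onset latencies and shape
  values, with box constraints keeping `alpha, beta > 0`; non-convergence
  from every start raises an error rather than returning a poor fit.
* Strict inequalities at all rule boundaries (< 100 ms merge, < 600 ms
  discard, < 70 voxels removed), as specified; exactly-at-boundary cases
  are covered by tests.
* Degenerate inputs (flat traces, zero-variance seeds, empty ROIs,
  all-zero contrasts) raise informative errors; a flat trace yields an
  empty event array rather than an error in `detect_events()`, since "no
  waves" is a valid observation.

# Validation problem sizes

The test suite validates wave-parameter recovery on single 30-min
sessions (about 320 waves), rate and count recovery on 10 such sessions,
HR recovery on one 30-min BOLD session (about 300 events, 16 x 16 x 6
grid), and the specificity controls on twenty 20-min sessions; null
calibration uses a 10,164-voxel white-noise session.  These sizes keep
the full suite under a few minutes while leaving Monte-Carlo error well
inside the asserted tolerances.

# What passing tests do and do not show

The generator plants stereotyped waves with log-normal parameter
variability, sinusoidal drift, white photometry noise, and spatially
homogeneous AR(1) BOLD noise.  Real recordings add photobleaching,
motion and susceptibility artifacts, heterogeneous hemodynamics, vascular
structure, and non-stationary anesthesia depth — none of which are
modelled (and spatial realignment, normalization and ICA are out of
scope).  Passing recovery tests therefore demonstrates the correctness
and calibration of the estimators under the stated model, not robustness
to every artifact of in-vivo data.
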