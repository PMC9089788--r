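---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

atriakit reimplements, as a tested pipeline, the quantitative
electrophysiology workflow used to characterise mice with atrium-selective
deletion of both AMPK catalytic subunits (AMPK-dKO): optical
action-potential mapping of Langendorff-perfused hearts (activation,
upstroke velocity, APD75), signal-averaged surface-ECG interval
measurement, atrial-fibrillation and ectopy classification, R-R
variability, and the delta-delta-Ct arithmetic behind the atrial
transcription-factor gradients. Because no raw recordings are publicly
deposited for this kind of experiment, the package ships a synthetic-data
generator whose control (CON) and knockout (dKO) presets encode the
reported effect sizes as ground truth; every downstream stage is validated
by recovering them end to end.

## The synthetic optical movie

Each pixel of the 80 x 80 field (50 um pitch, 1 ms frames, 10 Hz pacing,
cycle length 100 ms) fires one normalized action-potential template per
pacing cycle:

* a **linear upstroke** of duration `upstroke_rise_time`, centred on the
  pixel's activation time. A linear ramp is the one upstroke shape whose
  slope a sampled central difference recovers exactly, which keeps the
  ground-truth maximum slope (`1 / rise_time`) measurable at 1 ms frames;
* a **truncated shifted-exponential repolarization**
  `g(s) = (exp(-s/tau) - E) / (1 - E)` with `E = exp(-T/tau)`, where the
  full-repolarization time `T` (72 ms) makes the trace reach baseline
  exactly inside the cycle and `tau` is solved numerically so that the
  75%-recovery point falls exactly `apd75_true` after the maximum-slope
  instant. APD75 is therefore exact by construction, and diastole is a
  true isoelectric baseline — an untruncated exponential with these time
  constants would still carry 2-6% of the amplitude into the next beat's
  baseline window and corrupt the APD estimate.

The wavefront is planar by default, travelling from a pacing electrode
placed 21 pixel pitches (1.05 mm) outside the left field edge — far enough
that even the earliest pixel's upstroke foot starts after the stimulus —
at the preset conduction velocity; a `point` geometry (concentric fronts)
and a `simultaneous` flag (equal activation everywhere) exist for
fixtures. Dye polarity follows di-4-ANEPPS: fluorescence decreases on
depolarization, so raw movies are inverted downstream; polarity is
recorded in the sidecar, never assumed. Gaussian camera noise is added
per frame and the signal is quantized to integer counts (disable with
`quantize = FALSE` for analytic fixtures).

Only the dKO/CON ratios are anchored to the study's reported effects —
activation time x1.4, upstroke velocity x0.5, APD75 x1.5 — and they hold
exactly in the preset arithmetic. The paper reports no absolute control
values for these quantities, so the control preset uses physiological
choices for a young adult mouse: conduction velocity 0.5 mm/ms (a planar
wave crosses the 4 mm field in 8 ms), rise time 2 ms, APD75 30 ms. The
APD75 choice also respects the configuration invariant that the pacing
cycle be at least twice the APD75 for the knockout preset (45 ms).

## The optical processing chain

`prepare_beat()` runs the fixed order **segment -> ensemble-average ->
spatially smooth -> normalize/invert**:

1. `segment_beats()` cuts one cycle-length window per stimulus, aligned to
   the stimulus sample. Without stimulus annotations the pacing train is
   recovered from upstrokes of the global mean trace; such windows align
   to the tissue's mean upstroke (a few ms late) but keep the exact
   period.
2. `ensemble_average()` takes the pointwise mean of the first 8 complete
   beats ("8 consecutive" read literally, which also makes the result
   deterministic), shrinking i.i.d. noise by sqrt(8).
3. `spatial_smooth()` applies a 5 x 5 uniform kernel per frame with
   reflect padding (avoids amplitude bias at the atrial edge) and
   NaN-aware averaging restricted to the ROI.
4. `normalize_invert()` inverts (per polarity), subtracts the per-pixel
   baseline (mean of the last 10 ms before the stimulus — the shortest
   window safely inside diastole at a 100 ms cycle), and divides by the
   peak-minus-baseline amplitude, so traces rest at 0 and peak at exactly
   1. Pixels whose amplitude is below 5x the baseline-window noise SD
   (flat or signal-free pixels) are pruned from the ROI. Normalization is
   per pixel, not per field: per-pixel APD thresholds are meaningless
   otherwise.

## Map estimators

**Activation** is the instant of maximum first temporal derivative, the
standard optical-mapping upstroke convention. The derivative is sampled on
a dual half-frame grid: two-frame central differences at the frames plus
one-frame differences at inter-frame midpoints (themselves central
differences about `t + dt/2`). The midpoint estimates recover a linear
ramp's slope exactly at any phase relative to the frame clock; an
integer-only grid underestimates a 2 ms rise by up to ~10% with a
phase-dependent bias that would distort the CON/dKO velocity ratio.
Around the discrete maximum a clamped quadratic refinement gives sub-frame
timing; exact plateaus (noiseless ramps) are dated at their centre.
Derivative maxima at the window edge mark non-physiological traces: those
pixels become NaN and are counted in a quality report.

**Upstroke velocity** is the refined maximum derivative on the normalized
(0-1) trace, in 1/ms — absolute fluorescence units are arbitrary, and the
`amplitude_map` is preserved for anyone needing counts/ms.

**APD75** is the time from the activation instant to the first downward
crossing of normalized amplitude 0.25 after the peak, with linear
interpolation between samples; traces that never recover below the level
within the cycle are flagged NaN.

The field-wide **activation span** defaults to the 5th-95th percentile
spread (robust to single-pixel noise); `span = "minmax"` gives the full
range, used for the planar-wave geometry oracle, where the hand value is
(80 - 1) pixels x 0.05 mm / 0.5 mm/ms = 7.9 ms (a span covers n-1
interpixel distances). Whether the published "activation time" is a span
or a stimulus-referenced delay is not fully specified; the span is
primary here and the per-pixel stimulus-referenced delay is retained.

Residual knowns at the default 1 ms frames: an instantaneous upstroke has
a half-sample timing ambiguity, so the triangle-trace APD oracle is built
at 0.1 ms sampling where it reads 30.05 ms against the 30 ms closed form;
and 5 x 5 smoothing of a travelling wave dilates a 2 ms control upstroke
slightly more than a 4 ms knockout one, so the measured velocity ratio
sits near 0.53 noiselessly (ground truth 0.50) — within the 0.50 +/- 0.05
recovery band, with noise averaging it to ~0.50.

## The synthetic ECG

Beats are placed on a schedule whose instantaneous heart rate is Gaussian
(500 bpm, SD 10 bpm in control — minor physiological variability). P, QRS
and T deflections are raised-cosine templates with compact support
exactly equal to the preset durations, so on-disk durations equal ground
truth by construction. The fragmented ("double-peaked") knockout P wave
is the same envelope with a multiplicative central notch: its onset and
offset edges are identical in shape to the single-peak morphology, so the
noise-band fiducial rule treats both morphologies alike and the measured
duration spans first onset to last offset of the composite wave. The
knockout week-1 preset doubles P duration, prolongs PR by 10% and leaves
QRS unchanged, exactly, in the preset arithmetic.

Premature atrial complexes are 60%-premature beats with a fully
compensatory pause (intervals 0.6 m and 1.4 m around the mean R-R m). The
week-2-4 preset inserts 3 PACs per minute: with the control's 10 bpm HR
jitter, the closed-form variance of the resulting instantaneous-HR series
gives an SD ratio of ~2.98 vs control, matching the 3-fold target within
sampling error. Atrial fibrillation episodes replace P waves with a
random-phase fibrillatory oscillation (0.05 mV, ~15 Hz) and draw R-R from
a lognormal with CV 0.30 (floored at 45 ms). Recording noise defaults to
0.002 mV — recordings in a shielded chamber are near noise-free, and the
k x SD fiducial rule ties edge sensitivity directly to this value.

## ECG estimators

`detect_r_peaks()` band-passes (20-250 Hz Butterworth, zero-phase),
differentiates, squares and integrates over 10 ms, then keeps envelope
peaks above an adaptive threshold anchored to the upper quantile of
candidate peaks (QRS energy dwarfs P/T deflections) with a 20 ms
refractory period; R times are refined to the raw apex.

`signal_average()` averages 10 consecutive sinus beats whose R-R lie
within 10% of their median over a window of -0.6 to +0.4 R-R around R.
`measure_intervals()` estimates the baseline noise SD on the isoelectric
segment preceding the P wave and places fiducials at the first/last
sustained excursion beyond `k = 2` SDs (sustained = at least 2 ms, since
isolated noise samples cross a 2-SD band ~5% of the time), with linear
sub-sample interpolation; PR is P onset to QRS onset. The instrument's
internal onset/offset rule in the original workflow is unknown, so only
ratio-level comparisons are treated as reproducible. "At least 50
tracings per animal" is implemented by averaging measurements over all
qualifying sliding 10-beat windows (capped at 100); fewer than 50 sets a
quality flag rather than failing.

`detect_pac()` labels a beat premature when its R-R is below 80% of the
median of the previous five sinus intervals; beats inside detected AF
episodes are labelled `in_AF` and take precedence.

## The fibrillation rule and variability

The diagnosis rule is duration-based: disorganized atrial activity with
irregularly conducted QRS complexes lasting more than 30 s, in at least 2
separate 1-minute recordings on the same day. "Disorganized atrial
activity" is qualitative, so `detect_af_episodes()` operationalizes it as
the conjunction of (a) windowed R-R coefficient of variation above 0.15
(5 s windows, 1 s stride) and (b) no consistent pre-QRS P deflection: the
per-offset median of R-aligned pre-QRS segments, which preserves a sinus
P wave but cancels random-phase fibrillatory waves, compared against a
noise band estimated from mid-diastolic segments (which the fibrillatory
waves themselves inflate). Both thresholds are generator-calibrated
artifact decisions recorded in `af_criteria()`, not reported values; the
CV threshold sits about 7 SDs above sinus-with-ectopy variability and
half the fibrillatory CV. Flagged windows are merged and episodes must
exceed 30 s strictly, so a 20 s burst can never qualify even with window
overshoot (at most +4 s per side).

`hrv_metrics()` reports the SD of instantaneous heart rate (bpm) over the
first 60 s. Whether the published "standard deviation of the heart rate"
is beat-wise HR in bpm or R-R in ms is ambiguous; beat-wise HR in bpm is
primary and the R-R SD is also reported. Poincare pairs are consecutive
R-R couples: n beats give n-1 intervals and n-2 pairs.

## qPCR and statistics

`generate_ct_table()` encodes an atrial expression panel as true delta-Ct
values (target minus reference): a 160-fold left-right Pitx2c gradient in
control, a 60% left-atrial Pitx2c reduction in the knockout with the
right atrium unchanged, and a 1.75-fold Mef2c gradient abolished in the
knockout. `fold_change()` implements standard delta-delta-Ct
(`fold = 2^(-ddCt)`), which returns those design values exactly on
noiseless tables. `compare_groups()` is reporting plumbing only: Student's
two-tailed t test for two groups, two-way ANOVA with Holm-Sidak-adjusted
per-level contrasts for factorial designs (the Sidak step-down variant is
implemented directly, as base `p.adjust` offers only Holm-Bonferroni, and
is tested against hand enumeration).

## Problem sizes and validation scope

Recovery suites use 5 movies per genotype of 2 s each (the ensemble uses
the first 8 of 20 beats), 5-10 ECG recordings of 60 s per group, 100
sinus and 100 fibrillation recordings for classifier specificity and
sensitivity, and 1000 replicates for the t-test power oracle; unit
fixtures use small grids (8-40 rows) and fine frames where an analytic
value is asserted. These sizes give sampling error comfortably inside
each recovery band while keeping the full suite to a few minutes.

The generator emulates template-based periodic signals with stationary
Gaussian noise. It does not model motion artifact (the original
preparation used an electromechanical uncoupler), baseline drift,
beat-to-beat template variation, curved or re-entrant wavefronts,
multi-lead geometry, or rate-dependent restitution. Passing recovery
therefore demonstrates that the estimators are unbiased at realistic
noise under the stated morphology, not that they are robust to every
failure mode of real recordings; the quality flags and configurable
thresholds are the intended handles for real data.
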