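---
title: "ECG biomarkers of sympatho-vagal balance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG biomarkers of sympatho-vagal balance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiovag)
```

## What the package computes

`cardiovag` quantifies cardiac autonomic (sympatho-vagal) balance from
short multi-lead ECG epochs recorded with a four-electrode Wilson
tetrahedron (right arm, left arm, left leg, back). Three families of
biomarkers are produced per recording:

* **HRV indices** — mean RR, heart rate, and the LF (0.04–0.15 Hz) and HF
  (0.15–0.4 Hz) band powers of the RR series with their ratio. LF/HF is a
  (contested) index of sympatho-vagal balance; HF mainly reflects vagal,
  respiratory-gated modulation.
* **Deceleration capacity (DC)** — a phase-rectified signal averaging
  (PRSA) statistic of the RR series that isolates heart-rate
  *decelerations* and thereby indexes vagal modulation.
* **Periodic repolarization dynamics (PRD)** — the amplitude of
  low-frequency (≲0.1 Hz) oscillations of the spatial T-wave vector,
  an index of sympathetic modulation of ventricular repolarization that is
  not an epiphenomenon of HRV.

The pipeline per recording is:

1. **Preprocessing** (`preprocess_ecg`): zero-phase Butterworth band-pass
   2–26 Hz (order 4, applied forward–backward, reflect-padded), residual
   isoline removal (per-channel median), common-average re-reference.
2. **VCG transform** (`wilson_to_vcg`): per sample, lead differences
   (VL−VR, VF−VR, VB−VR) are mapped by a fixed 3×3 matrix (scale 1/22) to
   an unnormalized dipole projection; its unit normalization gives the
   direction cosines (px, py, pz), and the orthogonal components are
   (Vx, Vy, Vz) = 3·K·(px, py, pz) with the per-sample gain
   K = (1/33)·√(8·E² + VB²), E² = (VL−VR)² + ⅓((VF−VR)+(VF−VL))².
   The matrix entries and the constants of K live in a versioned
   coefficient file (`inst/extdata/wilson_vcg_coefficients.csv`), not in
   code: the published typesetting of these constants is ambiguous enough
   that a corrected transcription should be a data change. Every test of
   this module is valid for *any* fixed coefficient set (unit norm,
   gain invariance, round trip).
3. **Delineation** (`delineate`): R peaks from the vector magnitude
   √(Vx²+Vy²+Vz²) by a Pan–Tompkins-style energy detector (15 ms moving
   average of the squared magnitude, adaptive threshold at 0.4× the
   rolling 2 s maximum, 250 ms refractory); RR tachogram; the sequential
   20 % ectopic rule; and the QRS-anchored T-window rule
   Ton = R + 90 ms, Tend = R + min(360 ms, ⅔·RR).
4. **Biomarkers**: HRV from the cleaned tachogram (`time_domain`,
   `rr_psd`); DC via increment-anchor PRSA with half-window L = 12
   (`dc_from_tachogram`); PRD via the beat-to-beat T-vector angle series
   dT° (dot product of consecutive windowed mean T vectors), a 10th-order
   median filter, averaged-comparison anchors (M = 9), PRSA with L = 20,
   and the curve's max − min (`build_angle_series`, `prd_from_angles`).
5. **Cohort statistics** (`compare_conditions`): per biomarker, paired
   t-test between conditions with Shapiro–Wilk normality of the paired
   differences; raw p-values are the headline (no multiplicity correction
   across the seven biomarkers), with a Holm-adjusted column printed
   alongside as a clearly labelled extension.

## The PRSA core

PRSA extracts quasi-periodic structure from a nonstationary beat-indexed
series x by averaging fixed windows around *anchors*:

* increment rule (DC): i is an anchor when x\[i\] > x\[i−1\];
* averaged rule (PRD): i is an anchor when the mean of the M values
  starting at i strictly exceeds the mean of the M values before i.

Ties are **not** anchors (strict inequality as defined). The window spans
k = −L … L−1 with the anchor at k = 0 — this offset convention is fixed
here because "2L-sample window" alone does not determine it, and it
guarantees X₁ exists for every L ≥ 2. Anchors within L of *either* end
are discarded (the definition names only the last L samples, but a
two-sided window is equally undefined at the start), and windows that
contain an ectopic-flagged interval are dropped rather than interpolated.
Then

* DC = (X₀ + X₁ − X₋₁ − X₋₂)/4, in ms for an RR series;
* PRD = max(curve) − min(curve), in degrees for a dT° series.

L = 12 (DC) and L = 20 (PRD) are the defaults because they resolve the
oscillation bands of interest (0.04–0.15 Hz and 0.025–0.1 Hz
respectively at typical resting rates); both are plain config fields, the
L-to-frequency mapping is asserted by the method's originators, not
re-derived here. The classical DC practice of discarding anchors whose
prolongation exceeds 5 % is available (`exclude_prolongation_frac`) but
**off** by default, following the method definition as written.

Correctness of this core is established by oracle equivalence: both
anchor rules and the averaging are tested against independent naive
loop implementations on random series, with exact agreement required.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `filter$low_cut`, `high_cut` | 2, 26 | Hz | the method's stated analysis band |
| `filter$order` | 4 | — | Butterworth; effectively 8th order after forward–backward |
| `delineation$ectopic_threshold` | 0.20 | — | the 20 % rule, strict inequality |
| `delineation$twave_on_ms` / `twave_max_ms` | 90 / 360 | ms | QRS-anchored T-window rule |
| `delineation$twave_rr_frac` / `twave_rr_cut_ms` | 2/3 / 720 | — / ms | short-RR arm of the rule |
| `hrv$resample_fs` | 4 | Hz | even RR resampling before the FFT |
| `hrv$lf_band` / `hf_band` | 0.04–0.15 / 0.15–0.40 | Hz | standard HRV bands |
| `dc$L` | 12 | beats | DC half-window |
| `prd$L`, `prd$M` | 20, 9 | beats | PRD half-window and anchor-averaging span |
| `prd$median_order` | 10 | beats | dT° median filter (11-tap centered window) |
| `prd$tvec_floor_uv` | 2 | µV | validity floor for windowed mean T vectors |

Two details of the T-window rule are genuinely underdetermined and are
exposed as config switches with the defaults used throughout: `RRi` is
taken as the interval *preceding* beat i (`rr_mode = "preceding"`), and
the "QRS mark" that anchors the window is the R peak
(`qrs_mark = "r_peak"`). The "10th-order median filter" is read as an
11-tap centered window: an odd window has a unique center, which keeps
the filtered series aligned with the beat axis.

The ectopic rule's reference is initialized to the median of the first
five intervals rather than blindly accepting the first interval: a
recording that happens to open on an ectopic interval would otherwise
lock the scan onto a wrong reference and flag essentially every normal
beat. The scan itself is unchanged (strict 20 % deviation from the last
valid interval; flagged intervals never update the reference) and is
idempotent.

## Spectral estimation choices

The RR series is irregularly sampled in time, so `rr_psd` removes flagged
intervals, resamples the remainder at 4 Hz by cubic spline (the spline
bridges ectopic gaps, standard NN-series practice), detrends linearly,
applies a Hann window and computes a single-segment periodogram. Two-minute
epochs are too short for Welch averaging at 0.04 Hz resolution, hence the
single segment; all method metadata is recorded in the result. The
normalization is Parseval-consistent (the integral of the one-sided PSD
matches the windowed variance of the detrended series), and band powers
are trapezoidal integrals with interpolated band edges, so disjoint bands
sharing an edge add exactly. LF/HF with zero HF power is reported as
undefined, never as infinity.

## What the synthetic generator emulates — and what it does not

`generate_tachogram` builds RR series as mean + LF sinusoid + HF sinusoid
+ white jitter, with ectopic events inserted as an isolated 30–50 %
early beat plus a fully compensatory pause — exactly the discontinuity
the 20 % rule targets. `generate_vcg` places Gaussian-lobe P/QRS/T
templates (Q and S as negative side lobes) at the beat times; the T-wave
direction of beat i is the base direction rigidly rotated by
A·sin(2π·f·tᵢ) about a fixed axis orthogonal to it. A rigid rotation
preserves T amplitude, so the injected signal is purely the angle signal
PRD measures. `project_to_wilson` inverts the lead-difference map to
produce four surface channels (common-average consistent), then adds
per-channel baseline offsets and white noise. Every recording carries
machine-readable ground truth: R-peak samples, true RR and ectopic flags,
and per-beat T-vector directions and rotation angles.

Default study conditions (one choice, used everywhere): mean RR 800 ms;
LF 38 ms at 0.10 Hz and HF 38 ms at 0.25 Hz (band powers ≈ 720 ms² each);
jitter 10 ms; 2 % ectopics; fs 250 Hz (the recording hardware's rate is
not fixed by the method, so it is a config field); QRS 1.45 mV, T 0.4 mV
peaking 320 ms after R; T-vector oscillation 0.05 Hz, 8° at rest and 16°
under stress; channel noise 1 µV RMS. The RR-side numbers reproduce the
reported resting cohort means (RR ≈ 800 ms, LF ≈ 725 ms², HF ≈ 712 ms²,
HR ≈ 76 bpm) through the full pipeline.

Two deliberate idealizations deserve emphasis:

* **Concordant axes.** P, QRS and T share one spatial direction by
  default. The 2–26 Hz band-pass removes each wave's DC content, so the
  windowed mean T vector is a small residual of large cancelling lobes;
  with discordant axes, ordinary RR variability moves the filter ringing
  of neighbouring waves through the T window and produces degree-scale
  dT° noise that both masks an injected rotation and makes the PRD floor
  insensitive to channel noise. Healthy-adult repolarization is broadly
  concordant, and the concordant default makes the additive channel noise
  the dominant floor — so the noise-floor property (PRD decreasing as
  noise decreases) is actually testable. Real recordings have partial
  discordance; PRD levels here are therefore *lower* than the ~0.4°
  reported on real cohorts, and absolute PRD levels from this generator
  should not be compared against clinical values.
* **No respiratory coupling beyond HF RR modulation**, no baseline
  wander beyond static offsets, no pathological morphologies, no
  conduction-system model. Passing tests demonstrate the *pipeline's*
  correctness and sensitivity under known ground truth, not the clinical
  performance of the biomarkers.

The T-vector validity floor is 2 µV by default (config `tvec_floor_uv`):
after the 2–26 Hz band-pass, clean windowed T means sit at 5–20 µV, so a
more aggressive floor would reject entire clean recordings.

## Numerical conventions

* ms→samples rounding is nearest-integer with ties up (`floor(x + 0.5)`),
  fixed so fiducials are platform-stable.
* Forward–backward filtering uses reflect padding of 3× the nominal
  impulse span of the low cutoff; a symmetric pulse's peak does not move
  by even one sample, and DC is attenuated below 1e−6.
* Samples where all three lead differences vanish have no dipole
  direction; they are flagged `undefined` and bridged by linear
  interpolation (isolated zero crossings are numerically inevitable and
  physiologically meaningless). More than 5 % undefined raises a quality
  warning, more than 50 % an error.
* dT° is unsigned (arccos of a clamped normalized dot product, range
  0–180°): the dot-product construction carries no sign, and no attempt
  is made to orient the angles.
* Angle-series pairs that straddle a dropped or ectopic beat are excluded
  rather than bridged, and the beat-time axis keeps real timestamps so the
  oscillation frequency content is preserved.
* Degenerate paired comparisons (zero-variance differences) are flagged
  explicitly instead of reporting p = 0 or p = NaN.

## Problem sizes used in the shipped tests

The test-suite and acceptance studies run 2-minute epochs at 250 Hz
(≈150 beats): PRSA oracle equivalence on 100 random series of length
300–1000; a 20-seed amplitude sweep (0.1°, 0.2°, 0.4°, noise-free) for
PRD monotonicity; and 20 replicate paired cohorts of 17 subjects for the
rest/stress contrast, where the stress condition doubles the T-vector
oscillation amplitude and nothing else. These sizes mirror the intended
study design (17 analyzable subjects, 2-minute epochs) while keeping a
full run in the order of minutes on one CPU.

## Known limitations

* The Wilson-tetrahedron transform constants are transcribed from an
  ambiguous published typesetting; they are isolated in a data file and
  all structural tests hold for any fixed transcription, but absolute
  VCG magnitudes inherit that uncertainty.
* PRD is reported in degrees (the convention of the defining cohort
  table); parts of the PRD literature use deg². No conversion is
  attempted.
* T-wave delineation is the QRS-anchored window rule only — the rule the
  original analysis itself fell back to when peak-based multichannel
  delineation failed on low-amplitude or inverted components. Peak-based
  T delineation is out of scope.
* The paired comparison assumes matched rest/stress epochs per subject;
  subjects missing a condition are dropped with a message.
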