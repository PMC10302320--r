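---
title: "Signal quality assessment for hand-held single-lead ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal quality assessment for hand-held single-lead ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisqa)
```

## The problem

Hand-held ECG sticks with dry metal electrodes are used for large-scale
atrial fibrillation (AF) screening: the subject grips two metal handles and
the device records roughly one minute of the Einthoven-I lead at 200 Hz,
classifying the rhythm on-chip from RR-interval dispersion. Compared with
gel-electrode clinical ECG, these recordings are systematically distorted
(a capacitively coupled input stage acts as a first-order high-pass),
prone to motion artifacts (no adhesive contact) and sometimes inverted
(device held the wrong way round). Misclassification risk concentrates in
recordings of poor signal quality, so an automated, continuous
signal-quality index lets a screening workflow repeat bad measurements or
route them to human overread.

`aisqa` implements such an index end to end: a physical model of the
measurement chain, a synthetic-recording generator for testable ground
truth, artifact/inversion/peak preprocessing, a 22-feature multi-domain
description, and a Gaussian-process regression onto a continuous quality
score on [0, 3] (0 = excellent, 3 = uninterpretable), plus the metric suite
used to evaluate it.

## The measurement-chain model

The skin-electrode interface of each hand is a parallel RC (stratum-corneum
resistance `R_sc`, capacitance `C_sc`). The stratum-corneum capacitance is
approximated by a coaxial-capacitor formula in the electrode geometry
(length 4.5 cm, radius 1.1 cm) with SC thickness 10-800 µm and relative
permittivity 1e3-1e5 depending on skin humidity; over that grid the
capacitance spans tens of nF to hundreds of µF, so the interface is not the
morphology-limiting element. The limiting element is the coupling
capacitance `C_cpl` against the amplifier input resistance `R_in` = 50 GΩ:
a first-order high-pass with cutoff `1/(2π R_in C_cpl)`, i.e. 0.032 Hz at
100 pF up to 32 Hz at 0.1 pF. `transfer_function()` solves the full
divider (two skin interfaces in series with `C_cpl` into `R_in`);
`simulate_measurement()` discretises it with the bilinear transform at the
signal's sampling rate, which preserves the low-frequency pole position at
200 Hz sampling. The measured node is taken across `R_in`; DC is handled
analytically (gain 0).

Morphological consequences, reproduced by `morphology_sweep()`: as `C_cpl`
falls, the R amplitude drops, the isoelectric line is reached earlier, and
the T wave first looks sinusoidal and then acquires a negative lobe.

## The synthetic generator — and what it does not emulate

No public dataset matches this device class, so every downstream stage is
developed against `synthesize_recording()` /`generate_dataset()`. One
recording is: sum-of-Gaussian P-QRS-T template beats (R peak normalized to
1 mV before distortion) placed at RR-derived positions; the RR series is a
slow AR(1) modulation (cv 0.03) for sinus rhythm or memoryless i.i.d.
log-normal draws (cv 0.24, no serial correlation) for AF, whose beats also
carry no P wave; the clean trace is passed through the circuit model,
Gaussian broadband noise at a configured SNR and a 50 Hz tone (study region
mains) are added; artifact windows are overwritten with one of three
archetypes (broadband burst, baseline jump, rail saturation); inversion
multiplies by -1.

Two generator defaults deserve explanation:

* **Coupling capacitance 0.3 pF** (cutoff 10.6 Hz). This is the operating
  point at which the device-like morphology emerges, and it is also the
  regime in which the lead-inversion rule below actually works: with mild
  coupling (≥ 1 pF) an upright ECG does not satisfy `mean < median` for any
  beat shape we tried, because the positive R spike dominates the amplitude
  distribution's tail.
* **Deep S wave (-0.45 of the R amplitude).** Under a strong high-pass the
  dominant rare deflection of a distorted upright beat must be negative for
  the amplitude-distribution inversion test to hold; with this template the
  rule identifies upright recordings in 100% of seeds at ≥ 20 dB SNR across
  55-95 bpm (about 80% at 3 dB, where the label is "uninterpretable"
  anyway).

The **quality label** is a documented monotone stand-in for expert rating:
the worse of an SNR grade (≥ 20 dB → 0, 12-20 → 1, 5-12 → 2, < 5 → 3) and
an artifact-fraction grade (0 / ≤ 10% / ≤ 40% / > 40%). The default label
mix of `generate_dataset()` (11.83 / 67.97 / 19.10 / 1.10 %) follows the
prevalences reported for a 7031-recording pharmacy screening cohort.

What the generator does **not** emulate: atrial f-waves and other detailed
atrial activity, respiration coupling, electrode electrochemistry
(half-cell potentials, polarization noise), amplifier nonlinearity, and —
most importantly — the human expert: real quality labels come from
subjective overread with its own biases. Tests passing on synthetic data
therefore demonstrate internal consistency of the pipeline and
recoverability of a known corruption process, not clinical performance.

## Motion-artifact detection

The signal is cut into non-overlapping 5 s windows (≈ 5 beats at 60 bpm;
the trailing remainder is dropped). Each window is fingerprinted twice:

* **Amplitude domain**: the eCDF evaluated on a 100-point grid spanning the
  recording's min-max range (shared across windows).
* **Frequency domain**: the normalized cumulative amplitude spectrum of a
  Welch estimate with 0.5 s Hann sub-windows at 50% overlap (a
  "spectral-shape CDF").

For each window, Pearson correlations against all other windows are sorted
descending and the top N = 5 are averaged (`CCmax`); a window is flagged as
corrupted when either representation's `CCmax` falls below the threshold
0.982 — the conservative fusion maximizes artifact recall. Flagged windows
are discarded; the longest remaining run of clean windows must reach 30 s
(guideline minimum for rhythm assessment), otherwise the recording is
excluded. Equal-length runs tie-break to the earliest. A zero-variance
fingerprint gets correlation 0 with a warning rather than an error.

The frequency fingerprint is the one place where the obvious
implementation fails quantitatively: raw per-window magnitude spectra of
clean ECG correlate at only ≈ 0.65, because physiological RR jitter shifts
the harmonic lines between windows; against a threshold as high as 0.982
every window would be flagged. Integrating a sub-window-averaged amplitude
spectrum removes the line structure while preserving gross spectral
redistribution: clean windows (including AF and including 3 dB SNR
recordings) correlate ≥ 0.99, while burst and saturation windows fall
below 0.95 and baseline jumps are caught by the eCDF representation. A
consequence worth knowing: the detector is a *consensus* method — it
assumes artifacts are a minority of windows. Three look-alike bursts in
one recording can validate each other through the top-5 average and
escape flagging.

## Inversion, peaks, gating

After segment selection the lead polarity is checked: a correctly aligned
recording satisfies `mean(s) < median(s)` (the heavy tail of the distorted
beat is negative); otherwise the signal is negated and flagged. The tie
`mean == median` is treated as inverted (strict reading of the rule). The
check is a single global statistic, so it is applied once — it is
idempotent on R-dominated signals.

R peaks are found with a Pan-Tompkins chain: zero-phase 5-15 Hz Butterworth
band-pass, derivative, squaring, 150 ms moving-window integration, adaptive
dual thresholds with 200 ms refractory and a search-back pass at half
threshold for gaps exceeding 1.66× the median RR. Detections are refined to
the local maximum of the input signal in an asymmetric window (further back
than forward, compensating the causal envelope lag), and detections far
below the typical R height (< 0.35× the median peak amplitude) are pruned —
these are secondary humps of the distorted beat. A recording whose median
instantaneous heart rate leaves [40, 150] bpm is declared invalid
(`hr_out_of_range`); failures are reported as reason codes, never as NaN
feature rows.

## Morphology prototypes

Beats span R-to-R (half-open) and are linearly resampled to 200
heart-cycle-percentage points, making morphology comparable across heart
rates; pointwise mean and SD over beats give the recording's averaged
morphology. Reference ("ideal") prototypes are built from *excellent*,
sinus-rhythm recordings only: their averaged morphologies are compared by
dynamic time warping (absolute-difference local cost, unit steps,
Sakoe-Chiba band of 10% — unconstrained DTW is available via `band = 1`)
and partitioned into k = 4 groups. Because a mean is not defined in the
DTW space, the partition uses k-medoids (PAM) on the precomputed distance
matrix — PAM's build/swap search is deterministic, so no restarts are
needed — and each cluster is then summarised by the pointwise average of
its members. Prototype selection encodes "high coverage, low variance" as
a greedy rule: clusters join in increasing order of mean pointwise SD
until cumulative membership reaches 90%. Downstream similarity features
use the best match (minimum DTW distance) over the selected prototypes,
after normalizing cycles to unit R amplitude.

## The 22 features

Four families, fixed order (`aisqa_feature_names`): statistical (mean,
median, SD, bias-corrected skewness, raw kurtosis — normal → 3; constants
degrade to 0 by convention), time-domain (mean HR, SDNN in ms, valid
coverage `T_seg` in s, mean eCDF `CCmax`, DTW distance between the averaged
morphologies of the recording's two halves), frequency-domain (mean
spectral `CCmax`, and Welch band-power ratios with 4 s Hann windows at 50%
overlap — baseline SQI `1 − P(0,1)/P(0,40)`, QRS SQI `P(5,15)/P(5,40)`,
power-line SQI `1 − P(49,51)/P(1,60)` for 50 Hz mains, in-band SNR
`10·log10(P(5,40)/P(40,100))` dB, and their arithmetic mean), and
morphology-related (mean R amplitude in mV — the only amplitude-carrying
morphology feature; mean template SD; Euclidean, cityblock and DTW
distances plus Pearson correlation to the best prototype, all on
normalized cycles so they measure shape). Statistical features are
computed after inversion correction, on the valid segment. The SQI band
definitions follow the common forms of the ECG-quality literature; since
no exact formulas are fixed by the application, any deviation only shifts
feature scales, which the regression absorbs.

## The quality model

`aisqa()` fits a Gaussian-process regression from the standardized
features (centering/scaling is essential with mixed-unit features and
isotropic length-scales) to the labels treated as real values on [0, 3].
Three stationary kernels are available — absolute-exponential (the usual
"exponential kernel", Matérn ν = 1/2), Matérn 5/2, and rational quadratic —
with hyperparameters (length-scale, signal variance, homoscedastic noise
variance, and the RQ shape) fitted by marginal-likelihood maximization
(multi-start L-BFGS on log parameters, seeded; a 1e-8 jitter stabilises
the Cholesky). The noise term is fitted rather than pinned because the
reference labels are themselves noisy. Out-of-fold predictions from a
label-stratified 5-fold cross-validation are stored and reported by
`summary()`/`plot()` — reported CV metrics are always out-of-fold, never
in-sample. Predictions are the posterior mean clipped to [0, 3];
`predict(..., se.fit = TRUE)` adds the posterior SD and `simulate()` draws
from the posterior. Holdout evaluation uses `split_holdout()`, a
label-stratified seeded 20% split.

## Evaluation suite

`regression_metrics()` (RMSE, MAE, Pearson ρ; correlation against a
constant vector is an explicit error), `interpretability_roc()` (positive
class = uninterpretable, trapezoidal AUC), `balanced_accuracy_at()`
(operating point defaults to the Youden-optimal threshold, since no fixed
threshold is canonical; the threshold used is returned),
`subgroup_roc()` (one model per feature family on a shared split/kernel/
seed for comparability), `repeat_threshold_curve()` (301 thresholds on
[0, 3]; fraction repeated vs remaining false decisions), and
`false_decision_correlation()` (point-biserial ρ with p-value). On
synthetic data a "false decision" is a device-rule decision that
contradicts the generator rhythm, or any decision made on a grade-3
recording.

## Numerical choices and degenerate inputs

* Bilinear discretisation at the signal's `fs`; DC gain handled exactly.
* eCDF grid: 100 points over the recording range; windows are non-
  overlapping (consistent with the ≈ 5-beats-per-window arithmetic).
* DTW: band ≥ |n−m| is enforced so corner-to-corner paths always exist.
* PAM on an all-zero distance matrix (all morphologies identical)
  degrades to a single cluster with a warning.
* Validation problem sizes: the bundled validation suite uses 200-seed
  artifact/AF batches, 50-seed peak-detection batches, a 500-recording
  label-recovery experiment and 10×80 recordings pooled (≥ 200 per grade)
  for the grade-monotonicity check; these sizes give binomial/correlation
  confidence comfortably inside the asserted margins while keeping the
  suite quick. In the artifact-recovery check, a window counts as part of
  an injected burst's ground-truth cover when it holds at least 0.25 s of
  the burst — one QRS complex worth; a spill of a few samples does not
  corrupt a window.

## Known limitations

* The expert-rating process is emulated by an explicit monotone rule;
  nothing here validates agreement with human raters.
* The artifact detector's consensus assumption fails when most windows are
  corrupted alike; such recordings may pass undetected (they are usually
  caught later by the HR gate or score poorly).
* Device formats: recordings are read from CSV (`time_s,amplitude_mv`);
  the binary waveform formats of specific vendors are out of scope.
* The on-chip AF classifier is proprietary; the RR-dispersion stand-in
  (IQR/median > 0.12) reproduces only its documented principle.
* Quality scores are calibrated to the synthetic label scale; applying the
  shipped prototypes/models to real device data requires retraining on
  expert-labelled recordings.
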