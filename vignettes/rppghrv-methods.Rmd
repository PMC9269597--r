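---
title: "Methods: contactless heart-rate variability from facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless heart-rate variability from facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Heart rate variability (HRV) — the beat-to-beat variation of the
inter-heartbeat (NN) interval — is conventionally measured with an ECG or a
contact photoplethysmogram (PPG). The same pulsatile signal also modulates
the colour of facial skin: each systole slightly reddens the skin as blood
volume rises. `rppghrv` implements a remote-PPG pipeline that recovers this
signal from ordinary video (nominally 30 fps, ten-minute recordings), turns
it into NN intervals, computes a full HRV feature catalogue, and
quantifies how well the video-derived features agree with those from a
simultaneously recorded contact PPG.

The package has two halves: the measurement pipeline itself, and a seeded
synthetic-data generator that produces paired recordings with known
ground-truth beat times, so every stage can be validated without human
subjects.

# Pipeline

## Region of interest

The face is located per frame and cropped before any signal extraction.
Two ROI sources are supported. The `fixed` source takes one caller-supplied
box, which is the right choice for synthetic clips (their flat, uniform skin
patch carries none of the texture a feature-based face detector needs) and
for recordings with a known, static framing. The `auto` source is a
skin-chromaticity detector: pixels are classified as skin when red-dominant
(`R > G + margin`, `G >= B`, `R` above a floor) and the largest 4-connected
skin component's bounding box is taken, with the largest-area component
winning when several compete. Frames with no detection carry the last
successful box forward (frames before the first hit use the first
successful box), preserving track length.

Raw detections jitter by a pixel or two even on a motionless subject, which
would leak motion noise into the colour signal. The track is therefore
stabilized by a translation threshold: the committed box moves only when the
raw box centre has drifted at least `translation_threshold_px` (default
10 px at 720p; scale with frame height) from the committed centre, and the
box size is frozen to the first box's size so every cropped frame has the
same shape. Boxes that extend past the frame edge after a jump are clamped
and padded by edge replication.

Coordinates are 0-based, half-open, origin top-left, stated explicitly to
keep detection, cropping and the generator in register.

## Eulerian colour magnification

A 1% colour modulation is invisible and numerically fragile; Eulerian video
magnification amplifies it before extraction. The implementation follows
the classic colour-magnification recipe:

1. spatial low-pass: a Gaussian pyramid (separable 1-4-6-4-1 blur and
   2x decimation, `level` times, reflective borders) applied per frame;
2. temporal filter: an ideal (brick-wall) FFT bandpass per remaining
   spatial location over the full clip — the pipeline is offline, so the
   sharp band edges and zero phase of the ideal filter are preferable to an
   IIR approximation;
3. amplify the band by `alpha` (per-channel gains available) and add it
   back after bilinear upsampling to the input size.

Defaults are `level = 4`, `alpha = 50`, band 0.67–3 Hz (40–180 bpm).
Processing stays in RGB rather than a luminance/chrominance space: only the
red channel is consumed downstream, and avoiding two colour conversions
keeps the operator exactly linear (`magnify(aX) = a magnify(X)`), which the
tests exploit. Spatially uniform inputs are invariant under the pyramid, so
a uniform in-band tone of amplitude `a` emerges with amplitude
`(1 + alpha) a` — the closed form used as an oracle. When a cropped ROI is
too small for the configured depth, the pipeline runner caps `level` at
`floor(log2(min(h, w)))`; calling `magnify_color()` directly with an
infeasible depth is an error.

## Pulse signal and peak detection

The rPPG signal is the spatial mean of the red channel of the cropped,
magnified clip, sampled at the frame rate; the PPG branch uses the oximeter
trace directly. Both are detrended (least-squares line) and band-passed to
0.67–3 Hz, then peaks are detected: local maxima that clear
`mean + k * sd` (default `k = 0.5`) and are at least `min_distance_s`
(default 0.33 s, a 180 bpm ceiling) apart, the higher peak winning a
conflict. The height rule adapts to the signal's own scale, which matters
for rPPG where the absolute amplitude depends on `alpha` and skin tone;
the spacing rule encodes the physiological maximum. Signal endpoints may be
peaks (a recording can begin mid-systole).

Peak-to-peak intervals become NN intervals after plausibility filtering on
the 300–2000 ms window: intervals below 300 ms are treated as spurious
double-detections and resolved by dropping the later peak; intervals above
2000 ms are treated as missed-beat gaps and dropped without merging their
neighbours, leaving a gapped series rather than a fabricated long interval.

Two heart-rate definitions coexist and are deliberately kept distinct:
the count-based rate `60 * n_peaks / duration` used for branch-agreement
error metrics (and its per-minute stratification over full 60 s windows),
and the HRV feature `hr_mean`, the mean of `60000 / nni`.

# HRV feature catalogue

`extract_all_features()` returns 63 named features: 15 time-domain, 36
frequency-domain (12 per spectral estimator) and 12 non-linear. The counts
are fixed by the catalogue, not by what happens to be computable: a family
that fails on a given series yields `NA` values flagged `missing`.

*Time domain* (15): `nni_count`, `nni_mean/min/max`, `nni_diff_mean`
(mean absolute successive difference), `hr_mean/min/max`, `sdnn`, `rmssd`,
`sdsd`, and `nn20/pnn20/nn50/pnn50` with a strict `>` threshold
(differences of exactly 20 or 50 ms do not count).

*Frequency domain* (3 x 12): for each of Welch, autoregressive (Burg) and
Lomb–Scargle estimators, the peak frequency, absolute (trapezoid-integrated)
power, relative power and log power of the VLF `[0, 0.04)`, LF
`[0.04, 0.15)` and HF `[0.15, 0.4]` Hz bands. Relative powers are
normalized by the sum over the three bands, so they sum to 1 per estimator.
Settings follow common HRV practice and are config-exposed:

* tachogram resampling at 4 Hz by natural cubic spline (linear fallback
  below 4 points, with a warning) for the two uniform-grid estimators;
* Welch: 256-sample (64 s) Hann segments, 50% overlap, zero-padded to 4096
  bins — a 0.0156 Hz resolution kernel with ~0.001 Hz grid spacing;
* AR: Burg order 16, spectrum evaluated on 8193 grid points. The dense grid
  matters: near-deterministic modulation drives Burg poles close to the
  unit circle, and integrating the resulting narrow peaks on a coarse grid
  biases band powers noticeably;
* Lomb–Scargle: the classical tau-shifted least-squares periodogram on the
  uneven `(time, interval)` pairs, 4x oversampled, rescaled so its integral
  over the evaluated grid equals the sample variance of the intervals —
  an explicit variance normalization that makes absolute band powers
  comparable with the uniform-grid estimators.

*Non-linear* (12): Poincaré SD1/SD2 (via the variance identities
`SD1^2 = var(diff)/2`, `SD2^2 = 2 var(x) - var(diff)/2`), their ratio,
ellipse area `pi SD1 SD2`, CSI (`SD2/SD1`), CVI (`log10(16 SD1 SD2)`),
`SD2/SD1` again under its conventional name `sd2_sd1_ratio`, the lag-1
autocorrelation of the intervals, sample entropy (`m = 2`, `r = 0.2 sd`,
strict Chebyshev tolerance, self-matches excluded) and the three DFA
exponents (alpha1 over 4–16 beats, alpha2 over 16–64, overall). Degenerate
cases are reported as missing, never as silent zeros: `sd_ratio` when
`SD2 = 0`, sample entropy when no template pair matches, alpha2 when the
series is shorter than four times the largest scale.

On short-scale DFA a caveat worth stating: for uncorrelated data the
alpha1 window (4–16 beats) carries a known upward bias of roughly +0.05 to
+0.15, so validation of the white-noise scaling uses `alpha_overall`, whose
wider window dilutes the small-scale bias.

# Dual-source comparison

The oximeter and the camera do not start and stop together, so the longer
member of each pair is trimmed by the same amount at the beginning and at
the end (an odd surplus sample comes off the end) before detection. Heart
rates are compared with Me (signed mean difference — the sign is
informative and retained), MAE, SD of the differences and RMSE, globally
and per minute; the report also carries the SDs of the two rate vectors
themselves, since "SD" in agreement tables is ambiguous between the two
referents and the two can differ wildly.

Each of the 63 features is correlated across samples between sources with
Pearson, Spearman and Kendall tau-b tests (two-sided, normal-approximation
p-values so ties are handled uniformly). Each test's p-values are adjusted
with Benjamini–Hochberg over its own family of 63 (per-test families, not
pooled across tests), and a feature counts as significant only when its
q-value is below the threshold under all three tests. The default threshold
of `q < 0.5` is unusually permissive for an FDR criterion; it is the
package default deliberately, and config-exposed for stricter analyses.

# The synthetic generator and what it does (not) show

Ground-truth RR series come from integral pulse frequency modulation: the
instantaneous rate `r(t) = r0 (1 + a_LF sin 2 pi f_LF t + a_HF sin 2 pi
f_HF t)` is integrated in closed form and a beat fires at each integer
crossing. IPFM is the standard forward model for spectrally controlled RR
series: the band powers of the generated tachogram are set by the
modulation amplitudes, which the spectral estimators must then recover.
Gaussian beat-time jitter adds a broadband floor when wanted. Defaults
place `f_LF = 0.1` Hz, `f_HF = 0.25` Hz with fractional amplitudes of 0.05
— chosen for testability (clearly resolvable tones over ten minutes) rather
than fitted to any population, since amplitudes in-band are not otherwise
constrained.

The PPG emulator renders one unit Gaussian bump (sigma 50 ms) per beat plus
white noise; the video emulator renders a static mid-gray background, a
uniform skin-tone rectangle, and a red channel inside the ROI equal to
`baseline (1 + depth * pulse(t))` plus optional noise. Frames are floats by
default: a 1% modulation of an 8-bit value is below one quantum, and float
frames keep quantization error out of unit tests; `write_frames()`
quantizes explicitly when PNG output is requested.

What passing tests on this substrate do show: the spectral estimators,
peak detector, magnification and comparison statistics are numerically
correct and the pipeline is self-consistent end to end. What they do not
show: robustness to head motion, illumination drift, detector failures on
real faces, waveform-morphology effects (dicrotic notches), or ectopic
beats — none of which the generator emulates. The face-likeness of the
video is deliberately not emulated, because the downstream stages accept a
fixed ROI; the skin-chromaticity detector is exercised on synthetic skin
patches, and stands in for the feature-based cascade detectors used on real
footage.

# Validation scale and reproducibility

The packaged validation runs at desk scale on one CPU: the branch-agreement
battery uses ten paired 10-minute studies with 64x64-pixel frames (a 32x32
skin ROI), 30 fps video, 100 Hz PPG with 5% noise, 1% modulation depth and
mean heart rates spread over 55–90 bpm; the detector benchmark uses 45
10-minute PPG traces under the same RR conditions. These sizes exercise the
full ten-minute spectral window (the VLF band needs it) while keeping a
complete run in minutes. Every stochastic quantity is driven by an explicit
seed through an RNG-state-preserving wrapper, so identical arguments give
bit-identical studies and reports.

Known limitations, beyond the generator's idealizations: the ideal
temporal filter assumes offline processing (no streaming variant); a single
`alpha` is applied at one pyramid depth rather than a wavelength-dependent
attenuation schedule; multi-face scenes and facial landmarking are out of
scope; and normalized-unit LF/HF variants are intentionally absent from
the catalogue.
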