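---
title: "stp300: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stp300: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the simulated
world, the analysis model, the parameters that matter, and the numerical
and design decisions taken where the published description left the design
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The simulated oddball world

`simulate_paradigm()` reproduces the acquisition protocol of a low-cost
two-electrode (O1/O2, 128 Hz) visual oddball experiment: a 3 × 4 image
matrix, each image flashed 12 times per trial in a seeded uniform random
permutation, 6 trials, 200 ms flashes separated by 100 ms recesses. This
yields 864 flashes of which 72 are targets, at a stimulus-onset asynchrony
(SOA) of 0.3 s.

`synthesize_recording()` adds, at every target onset, three ERP components
modelled as Gaussian bumps `a·exp(−(t−ℓ)²/(2w²))`. Peak amplitude and
latency are drawn per event from normal distributions with the published
component means and standard deviations (P1 −6.29 ± 4.03 µV at
159.26 ± 45.98 ms; P2 5.62 ± 3.26 µV at 266.17 ± 63.03 ms; P3 8.72 ± 4.17 µV
at 478.65 ± 76.53 ms). The published statistics specify only peak amplitude
and latency, not morphology; the widths `w` = 20, 25, 40 ms are a package
choice, made once, so that (a) the three components remain resolved inside
a 700 ms epoch and (b) the summed waveform's energy falls in the 1–8 Hz
ERP band used for display filtering — a Gaussian bump of width `w` has
spectral scale `1/(2πw)` ≈ 8, 6.4, 4 Hz respectively. A latency drawn
outside the epoch is redrawn up to a bounded number of times, then clipped
with a warning.

Both channels receive the same ERP template with independent noise: the
source analysis treats the occipital pair as one signal and gives no
inter-channel information, so modelling a channel difference would be
invention without a test.

**Noise.** Background activity is `1/f^α` colored Gaussian noise (α = 1 by
default), frequency-domain shaped and rescaled to an exact RMS, plus an
optional 10 Hz idle-rhythm sinusoid (off by default). The RMS presets are
`clean` = 1, `paper` = 4 and `hard` = 8 µV. The 4 µV default is the
package's one free calibration of the stated world: it represents a
low-SNR consumer headset (component peaks of 6–9 µV against 4 µV RMS
noise) and was chosen a priori so that the pipeline operates in the
published 75–92 % accuracy regime; the SNR-monotonicity and chance-level
properties are tested against the other presets.

**Time base.** The recording starts at t = 0 at the first flash onset and
extends one SOA plus a 1 s padding past the last onset. The padding is
needed for the protocol arithmetic to close: the final target's 700 ms
epoch must be complete, otherwise only 71 epochs remain and the 50 s target
group (72 × 0.695 s = 50.06 s) cannot be assembled.

**Randomness.** One master seed expands into fixed independent substreams
(schedule, amplitudes, latencies, per-channel noise, subject factor), so
changing e.g. the noise model never perturbs the schedule; this is tested.

**Open question resolved.** Physiologically, non-target flashes evoke a
small visual response too; the source protocol is silent about it. The
generator defaults to none (`nontarget_scale = 0`) and exposes the scale as
a stress knob rather than a claim about its size.

## 2. Preprocessing and component statistics

The two channels are averaged into one occipital trace and the whole-trace
mean is subtracted (the one baseline correction the protocol prescribes; no
per-epoch baseline correction is applied). Target epochs are the
`floor(0.7 × 128) = 89` samples after each target onset — `floor` so an
epoch never reads past its nominal duration. The non-target "Group 2" is
everything else: consecutive, non-overlapping 89-sample slices excluding
any sample within 700 ms after a target onset, so no sample carries both
labels (tested as a partition property).

`detect_components()` takes P1 as the minimum sample in 100–210 ms and
P2/P3 as the maxima in 200–330 ms and 400–560 ms — the published mean ± 1 SD
latency ranges rounded outward. An epoch whose extrema violate the sign
pattern (P1 < 0 < P2, P3) is *discarded*, not an error, mirroring the
discard rule used for the published statistics. `component_stats()` then
reports per-component means, SDs and mean ± 1 SD latency windows; applied to
the printed latency means/SDs this reproduces the published window bounds
113.28–205.24, 203.14–329.20 and 402.12–555.18 ms exactly (acceptance
criterion 1).

**Known detection biases.** Windowed per-epoch peak picking is not an
unbiased estimator of the generating parameters, and the tests document
rather than hide this:

* *Sampling grid.* At 128 Hz a peak is sampled up to half a sample
  (3.9 ms) off its true latency, attenuating a bump of width `w` by up to
  `1 − exp(−(3.9 ms)²/(2w²))` (1.9 % for the 20 ms P1). The SOA of 0.3 s is
  not a whole number of samples, so even noise-free zero-variance epochs of
  the full schedule are sub-sample-shifted copies rather than identical.
* *Window clipping.* Latency draws land outside the ±1 SD search window
  ~27–32 % of the time; the detected peak then sits on the window flank,
  biasing amplitudes low (most visibly P2, whose 63 ms latency SD is large
  relative to its 130 ms window).
* *Edge asymmetry for P1.* Because the positive P2 flank raises the right
  side of the P1 window, epochs whose P1 lies beyond 210 ms often have
  their window minimum at the *left* edge, pulling the P1 latency mean a
  few ms early.
* *Epoch overlap.* Adjacent flashes are 0.3 s apart, and two successive
  flashes of the target image occur several times per experiment; the
  preceding epoch's P3 then leaks into the following epoch's P1 window.
  This is intrinsic to the random oddball schedule, and real recordings
  under the same protocol contain the same contamination.
* *Noise extrema.* Picking a windowed extremum of signal + noise biases
  amplitudes outward by an amount growing with the noise RMS.

The net effect at the acceptance settings (1 µV noise) is a P1 latency mean
around 146–159 ms against the generating 159.26 ms. This exceeds the
2-standard-error band (±10.84 ms) that acceptance criterion 3 allows at its
fixed seed, so that half of the criterion is an honest failure: the
criterion presumes windowed detection is unbiased, which the mechanisms
above contradict. The corresponding amplitude check (P3 within ±0.98 µV)
passes.

**Filtering.** No `signal`-package equivalent is assumed: `bandpass()`
applies the squared magnitude response of a 4th-order analog Butterworth
band-pass in the frequency domain (odd-reflection padding at the edges).
This has the identical amplitude response to forward–backward IIR filtering
(the usual "filtfilt" recipe), exactly zero phase — so component latencies
are untouched — and no start-up transient; the gain curve is verified in
the tests against values frozen from an independent filter-design oracle.
One octave outside the 1–8 Hz passband the attenuation is ≈ 55 dB.
Filtering is used for ERP display/averaging; component detection runs on
the unfiltered epochs, because a 1 Hz high-pass removes a substantial part
of a Gaussian bump's (low-pass) spectrum and would bias all amplitudes low.

**Grand averages.** The per-epoch statistics and the grand-average waveform
are reported separately and not forced to agree: latency jitter of ±46–77 ms
across epochs necessarily makes grand-average peaks much smaller than mean
per-epoch peaks (the source reports the same scale discrepancy without a
reconciliation procedure).

## 3. The discrete Stockwell transform

For a signal of length N the one-sided transform has voices
n = 0 … ⌊N/2⌋ at frequencies n·fs/N and all N time columns. Voice n ≥ 1 is
computed in the frequency domain as the inverse DFT over m of
`H[m+n]·G_n[m]`, where H is the DFT of the signal divided by N and
`G_n[m] = exp(−2π² m² /n²)` is the spectrum of the voice's unit-area
Gaussian window (summed over ±1 spectral periodizations, which bounds the
sampling alias below ~3 × 10⁻⁹ even at the Nyquist voice).

Numerical and definitional choices:

* **Normalization.** The printed window normalization |f|/(2π) is replaced
  by the classical |f|/√(2π): only the unit-area window makes the
  transform's time average equal the Fourier spectrum — an identity the
  source itself asserts and which the package tests to 10⁻⁸ for every
  signal tried. `window_scale` exposes the width multiplier for
  sensitivity checks.
* **Zero voice.** The window degenerates at f = 0; row 0 is defined as the
  constant signal mean.
* **DC leakage floor.** Every voice's window responds to a constant signal
  with exactly `exp(−2π²) ≈ 2.7 × 10⁻⁹` of its level (the Gaussian spectrum
  evaluated one voice away in units of its own width). A "zero response on
  non-DC voices" check below ~10⁻⁸ of the signal level is therefore
  mathematically impossible under this definition; the tests assert the
  10⁻⁸ floor.
* **Oracle.** `stransform_direct()` evaluates the defining time-domain sum
  with a circularly periodized sampled window (the number of periodizations
  scales with `window_scale`; the lowest voice's window has σ = N samples,
  so tails die off slowly in period units). FFT and direct paths agree to
  10⁻⁸ relative error on all tested signals — including odd lengths — and
  the transform is linear to 10⁻¹⁰.
* **Localization is frequency-dependent in voice units.** The window's
  spectral width is f/(2π) Hz while voice spacing is fs/N Hz, so a pure
  tone's energy spreads over ≈ f·N/(2π·fs) voices. The "≥ 90 % of energy
  within ±2 voices" property genuinely holds only for low voice indices
  (≈ ≤ 10); at voice 16 (8 Hz at fs = 128, N = 256) the within-±2 share is
  ~84 % by direct calculation. The property is tested where it holds, and
  this analysis is the reason.
* **No decimation.** All N columns are kept; `freq_range` restricts the
  computed voices (used by the pipeline to compute only the band of
  interest), subsetting exactly the rows of the full transform (tested).

## 4. Features

Band averaging takes the mean S-transform magnitude ("instantaneous
amplitude") over voices in half-open bands [low, high) — half-open because
the published band list names 5, 8, 15 and 30 Hz in both neighbours, and a
voice must belong to exactly one band (tested as a tiling property). The
DC voice is always excluded.

Windows are 2 s advanced by 0.25 s; the count ⌊(T−w)/s⌋+1 is checked
against a brute-force enumeration oracle. The five feature functions use
the common signal-processing conventions, since the source names the
functions without formulas: sample SD (n−1), skewness `m3/m2^1.5` and
Pearson kurtosis `m4/m2²` as raw moment ratios (not bias-corrected, not
excess), trapezoidal area under the (non-negative) band amplitude with
dt = 1/fs — so a constant-1 window of n samples has AUC (n−1)/fs — and mean
squared amplitude. Zero-variance windows make the moment ratios undefined;
such windows are dropped with a warning rather than erroring, since long
synthetic silences are legitimate.

## 5. Classification protocol and classifiers

The 50 s per-group signals are the temporal concatenation of the group's
epochs in acquisition order, truncated to exactly 50 s — adopted because the
arithmetic closes (72 × 0.695 s = 50.06 s ≥ 50 s) and no other construction
is described. The first 25 s of each group train the classifier; the second
25 s are cut into five 5 s segments per group and interleaved target-first
into the 10-segment alternating test sequence. The S-transform is applied
per contiguous same-label piece (two 25 s training halves, ten 5 s test
segments), giving 93 training windows per group and 13 test windows per
segment — 130 test points; accuracy is reported per window, matching the
per-window test markers in the source's scatter plots (the denominator is
never stated there; this is recorded as an interpretive choice).

Features are z-scored with training-set statistics before fitting — an
RBF scale of σ = 1 only makes sense on a normalized feature space — and the
same constants are reused at test time; the behaviour is switchable
(`standardize = FALSE`).

*LDA* is the two-class linear discriminant with pooled covariance and a
log-prior offset; a singular pooled covariance is ridge-regularized with a
warning. Its predictions are checked against an independent reference
implementation. *SVM* is a soft-margin C-SVC trained by a deterministic
maximal-violating-pair SMO on the dual (stopping gap 10⁻⁶), with kernels
linear, quadratic `(1 + x·y)²` (the polynomial family at degree 2) and RBF
`exp(−‖x−y‖²/(2σ²))` — the exact kernel form listed by the source, not the
γ parameterization — at σ = 1, C = 1. Training is deterministic (tested),
duplicated contradictory points raise a degenerate-input warning, and a
decision score of exactly zero is assigned to the non-target class
(conservative detection).

## 6. Pipeline, subjects and reproducibility

"Subjects" are independent seeds; each gets a multiplicative ERP amplitude
factor drawn from Normal(1, 0.1²) — a documented generator extension, since
inter-subject variability is otherwise unreproducible, and 10 % amplitude
scaling is a conservative stand-in for it. Identical configurations produce
byte-identical reports (tested); artifacts (per-combination accuracies,
grand means, provenance) are written as CSV/JSON. Recordings round-trip
through CSV exactly and through a minimal EDF+ implementation within its
16-bit quantization step of exactly 0.01 µV (fixed ±327.68 µV physical
range), with flash events in a standard annotations channel.

## 7. What a green test establishes — and what it does not

The synthetic world contains: the exact paradigm timing, per-event
component variability with the published statistics, 1/f noise with an
exact RMS, subject-level amplitude scaling, and the full protocol
arithmetic. It does **not** contain: ocular or muscle artifacts, electrode
impedance drift, non-stationary or non-Gaussian noise, inter-channel
asymmetries, latency correlations across components, or any non-target
visual response (by default). Classification accuracies on this world
(high 80s–90s at the default preset, degrading to ~75 % at the hard preset
and to chance at zero ERP amplitude) therefore validate the *pipeline
mechanics and its statistical behaviour* — signal-to-noise monotonicity,
chance-level calibration, protocol conservation — not the field
performance of the method on human data, for which no public recordings of
this experiment exist.
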