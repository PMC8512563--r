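---
title: "Identifying subjects from carotid artery sounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying subjects from carotid artery sounds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blood flow through the common carotid artery produces an audible signal
whose spectral content is hypothesized to be subject-specific: stable
across recordings of the same person and different between people.
`carotidprint` implements a complete analysis pipeline for testing that
hypothesis on mono 16 kHz auscultation audio: quality screening, a
time-scale spectral estimate, cardiac-cycle segmentation, per-cycle
spectral "fingerprints", and a small convolutional network evaluated under
stratified repeated k-fold cross-validation.

Because real carotid recordings of identified subjects are private
clinical data, the package ships a first-class synthetic generator
(`make_profiles()`, `simulate_recording()`, `simulate_dataset()`) that
emulates the relevant structure of such data and provides exact
ground-truth cardiac states for testing every downstream stage.

## The synthetic generator

Each simulated subject (a `carotid_profile`) combines:

* **Heart-sound transients.** S1 and S2 are Gaussian-windowed multi-tone
  bursts (S1 fundamental 28-40 Hz, S2 50-75 Hz, each with one overtone),
  with per-beat amplitude jitter (±15%) and pitch jitter (±15%) emulating
  beat-to-beat variability.  Durations are 90-130 ms (S1) and 70-100 ms
  (S2).
* **Flow sound ("murmur").** Band-limited noise in a subject-specific band
  placed between 4 and 100 Hz — the range where carotid spectra carry
  their discriminative structure — plus a narrow resonant component at the
  band center, because per-subject carotid spectra typically show peaked,
  narrow frequency components rather than flat noise.  The murmur is
  boosted by up to 1.9x during systole, and its overall level (RMS gain
  0.09-0.15 relative to the unit-amplitude S1) keeps the transients
  clearly dominant, as in good-quality auscultation.
* **Timing.** RR intervals are Normal with a per-subject mean heart rate
  (70-95 bpm resting range) and proportional variability, truncated at
  0.4 s.  The systolic interval scales with the RR interval; recordings
  start at a random cycle phase.
* **Devices and sides.** Four device "clones" differ by ±2 dB gain and a
  gentle first-order low-pass (3-6 kHz), reflecting hardware that is
  interchangeable for practical purposes.  The right side applies a small
  multiplicative gain (0.88-0.98) to the murmur, so left/right spectra of
  one subject remain very similar.
* **Degraded recordings.** A configurable fraction (default 9/890, the
  rejection rate the screening stage is calibrated to) has its S2 bursts
  attenuated to 5%, far below the flow-noise floor, so that S2 events are
  not recognizable.

Murmur-band centers are log-spaced; the `separation` parameter requests a
minimum spacing in octaves.  With seven subjects confined to 4-100 Hz the
available span (about 3.9 octaves of centers) cannot honor 0.8 octaves
pairwise, so the spacing is capped at the feasible value — the band limits
take precedence because they, not the spacing, are the physiologically
anchored quantity.

What the generator does **not** emulate: hemodynamic physics, pathology
(bruits, stenosis), breathing artifacts (recordings are modeled as
acquired under apnea), sensor placement variability, or long-term drift of
a subject's spectra.  Passing the package's tests therefore demonstrates
that the pipeline recovers subject identity when the data contain
band-limited spectral signatures of the assumed kind — not that real
carotid sounds contain such signatures.

## Quality screening

The screening stage automates a visual accept/reject judgment: a recording
is usable when S1 and S2 transients are recognizable.  A smoothed (50 ms)
envelope of the 25-400 Hz band is peak-picked (minimum inter-peak distance
0.2 s); beat-level peaks at least 0.75 heart periods apart are S1
candidates (with a refinement: a comparable peak 0.15-0.45 periods earlier
is taken as the true S1, since beat-to-beat jitter can make S2 the taller
transient), and the strongest peak in the 18-60% of-a-period window after
each S1 is the S2 candidate, accepted when it exceeds both 1.5x the median
envelope (the noise floor) and 25% of the typical S1 height.
A recording passes when at least 70% of the expected cycles (from the
autocorrelation heart-rate estimate) have both candidates.  All thresholds
are exposed as arguments; they are declared automation choices, not values
inferred from data.  Identification does not depend on this screen — the
pipeline offers a bypass flag.

## CWT with generalized Morse wavelets

Spectra are computed with analytic generalized Morse wavelets with shape
parameter gamma = 3 (the perfectly symmetric member) and time-bandwidth
product 60, hence decay parameter beta = 20.  The wavelet's peak radian
frequency `(beta/gamma)^(1/gamma) = 1.8821` maps scales to
pseudo-frequencies.  The transform is computed in the frequency domain on
a geometric scale grid (default 10 voices per octave), with symmetric
padding of about 3.7 slowest-wavelet periods per side to suppress edge
energy, and the **magnitude** is stored; log-compression happens only at
rendering time.  The default analysis band is 1-200 Hz: the discriminative
structure lies below 100 Hz, and a reduced band keeps the spectrum small;
full-band analysis (up to the 8 kHz Nyquist) is available by raising
`f_max`.

Inside `run_pipeline()` the audio is decimated to 2 kHz (8th-order
anti-alias low-pass) before the fingerprint CWT — a five-fold oversampling
margin for a 200 Hz band, and standard practice for low-frequency
phonocardiographic analysis.  Event detection and segmentation always use
the native 16 kHz audio.

## Cardiac-cycle segmentation

Segmentation assigns each 20 ms frame one of four states — S1, systole,
S2, diastole — with a duration-dependent hidden (semi-)Markov model:

* **Features** (50 Hz frame rate, computed on a 25-400 Hz band-passed,
  1 kHz-decimated copy, each min-max scaled per recording): homomorphic
  envelope (8 Hz low-pass of the log Hilbert magnitude), Hilbert envelope,
  a Morse-wavelet envelope at 60 Hz, and a 40-60 Hz band envelope.
* **Emissions**: one-vs-rest logistic regressions per state, normalized
  across states.  Training labels come from the generator's ground truth.
* **Durations**: truncated-Normal per state, estimated from interior
  labeled run lengths (edge-truncated runs are excluded).  At decode time
  the systole/diastole means are rescaled so the expected cycle length
  matches the heart rate estimated from the homomorphic envelope's
  autocorrelation (peak lag searched in 0.43-1.5 s; a 70 bpm prior with a
  warning when no periodicity exists).  The duration search is capped at
  twice each state's mean.
* **Decoding**: extended Viterbi over explicit segment durations on the
  fixed cycle S1 -> systole -> S2 -> diastole.  The first and last
  segments of a recording are scored with the duration *survival*
  function, since recordings start and end mid-state; interior segments
  use the duration pmf.  Ties resolve toward the earlier state in cycle
  order.  The dynamic program is verified against brute-force enumeration
  of all cyclic label sequences on toy instances.

Cardiac cycles are then cut from each maximal diastole-run start to the
next S2-run end, so a cycle is (diastole, S1, systole, S2); incomplete
edge fragments are dropped.

## Fingerprints and classifier images

The CWT magnitude is sliced at the cycle boundaries; each slice is resized
in time to 16,000 columns (1 s at 16 kHz) by nearest-neighbor
interpolation — output column *j* copies input column
`floor((j + 0.5) * w_in / w_out) + 1` — and pixel-wise averaging of all of a
subject's cycles yields the per-subject, per-side fingerprint.  Left and
right sides are processed independently throughout.

Classifier inputs are per-cycle images: magnitude is log-compressed as
`log(1 + m / (1e-3 * max(m)))` (exactly amplitude-invariant because the
reference is the image's own maximum), min-max normalized per image,
resized to 134 x 134 by nearest neighbor, and mapped through a fixed
256-entry jet-style RGB lookup table generated procedurally, so rendered
images are bit-stable.  The three-channel rendering is forced by the
classifier's first-layer parameter count (896 = 3x3x3x32 + 32 implies 3
input channels); the specific palette is a free choice.

## The classifier and its evaluation

The network is deliberately small: three 3x3 valid convolutions with 32
filters, each followed by 2x2 max pooling (feature maps
132 -> 66 -> 64 -> 32 -> 30 -> 15), a dense ReLU layer of 128 units and a
softmax output — 942,023 parameters in total, with per-layer counts 896,
9248, 9248, 921,728 and 903.  Training uses Adam (learning rate 0.001),
batch size 32, 10 epochs, categorical cross-entropy, Glorot-uniform
initialization.  Activation, optimizer, initialization and padding are
conventions chosen to reproduce the published shapes and counts; all are
configurable.  The implementation is single-precision im2col + GEMM in
compiled code, with every source of randomness (weights, batch order)
drawn from one seed, so confusion matrices reproduce exactly on CPU.

Evaluation uses stratified k-fold cross-validation with repetitions
(default 5 folds; 10 repetitions give the full 50 runs).  Splitting is
over cycle images, so cycles of one recording can appear on both sides of
a split — mirroring a per-sample randomization protocol; a stricter
grouped-by-recording mode is a documented possible extension, not the
default.  Per class, TP/TN/FP/FN are reduced one-vs-rest and
SEN/SPE/PRE/F1 and the per-class accuracy `(TP+TN)/(TP+TN+FP+FN)` are
computed; undefined 0/0 ratios are reported as missing, never as zero.
The headline accuracy is the multiclass trace/total, the only
single-number reading consistent with one accuracy per experiment; the
one-vs-rest accuracies relate to it analytically by
`mean(ACC_ovr) = 1 - (2/C)(1 - ACC)`.  Aggregation over runs reports the
arithmetic mean and the sample standard deviation across all runs, in
`(mean±sd)%` form with two decimals.

## Problem sizes and numerical choices

The package's reference experiment — also what `scripts/acceptance.R`
runs — simulates 7 subjects with murmur-band separation 0.8, 9 left-side
recordings of 11 s per subject (at least 80 segmented cycles each), trains
the segmenter on a held-out labeled set (2 recordings per subject), and
evaluates the CNN under 5-fold cross-validation with 2 repetitions.  These
sizes are the package's chosen defaults for a desk-scale study; the full
protocol (more recordings per subject, 10 repetitions) is a configuration
change, not a code change.

Other numerical choices: duration pmfs are normalized over their integer
support; emission probabilities are floored at 1e-12 before logs;
peak-normalization rejects all-zero signals as degenerate inputs rather
than producing NaNs; the resampler requires integer decimation factors;
fold assignment deals shuffled class indices round-robin so per-fold class
counts differ by at most one.

## Known limitations

* The synthetic generator is the only data source; all accuracy claims are
  about recovery of planted structure, not about real carotid sounds.
* The emission model is trained per experiment on synthetic truth; no
  pretrained segmentation weights are shipped.
* Identification (1-of-N) only; no verification (1:1 matching) mode.
* Device effects are mild linear perturbations; strong sensor
  nonlinearities or motion artifacts are out of scope.
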