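---
title: "Fall detection from surface EMG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall detection from surface EMG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfall)
```

## The problem

Falls are the dominant cause of serious injury in people over 65. Surface
electromyography (sEMG) measures the electrical activity of skeletal muscle
from skin electrodes; because muscle activation precedes and accompanies
movement, sEMG carries enough information to distinguish a fall from daily
leg movements such as walking, squatting and sitting down. `semgfall`
implements a complete recognition pipeline for four-channel sEMG recorded
over the main leg muscles (rectus femoris, vastus medialis, tibialis
anterior, gastrocnemius) at 1500 Hz, with *falling* as the positive class.

The pipeline is: band-pass denoising, energy-based extraction of the active
segment of each recording, short-time Fourier spectrogram features reduced
by PCA (plus the classic time-domain features for comparison), a
dual-parallel-channel convolutional network with ablation variants and
classical baselines, and leave-one-subject-out (LOSO) evaluation.

## Synthetic study conditions

The target study design is 10 subjects x 4 gestures x 10 repetitions = 400
recordings (100 falls). No such recordings are publicly deposited, so the
package ships a first-class generator, `generate_recording()` /
`generate_dataset()`, whose defaults *are* the emulated study conditions.

Each recording is zero-mean Gaussian baseline noise into which one activity
burst is embedded per repetition. A burst is band-limited Gaussian noise
(band-pass-filtered white noise) shaped by a trapezoidal envelope — this
reproduces the stochastic interference-pattern character of sEMG without
modelling individual motor units. Gestures differ in:

* **carrier band** — walking 20–150 Hz, squatting 30–250 Hz, sitting
  15–110 Hz, falling broad-band 10–450 Hz;
* **four-channel amplitude pattern** — each gesture has its own per-muscle
  weighting; falls are the highest-energy class and nearly simultaneous on
  all channels (co-contraction), while daily activities stagger channel
  onsets by up to 0.2 s;
* **envelope timing** — rise times 0.10–0.35 s and plateaus 1.2–2.0 s,
  drawn per repetition; recording durations are uniform on 3–5 s.

The class energy spread is deliberately kept within a factor of ~2.5
(amplitude patterns between ~0.5 and 1.5 relative units). Real leg-muscle
recordings of these actions have comparable intensities, and the static
energy thresholds of the segmenter (below) assume as much; class identity
is carried by spectral band, channel pattern and burst simultaneity — which
is also all the classifier can see after per-segment normalization.
Subject profiles (per-channel gain, baseline noise level, amplitude
modulation) are log-normal around 1 and deterministic given a seed, which
emulates inter-subject variability and makes every experiment reproducible.

Two separability settings are provided: `noise = "easy"` (baseline SD 0.06,
bursts 8-25x the noise floor) and `noise = "hard"` (baseline SD 0.45,
approaching the weakest bursts). All tests and worked examples use the easy
setting; the hard setting exists to probe degradation.

**Ground-truth annotation.** Each recording stores the interval where the
burst's deterministic combined RMS exceeds 3x the combined baseline noise
SD — the standard 3-sigma activity-onset convention. The trapezoid's ramps
start at amplitude exactly zero, so the envelope's mathematical support is
not a detectable onset and would make boundary-error evaluation a statement
about annotation, not detection. Bursts that never clear 3 sigma (e.g.
`amplitude_scale = 0` controls) are annotated as burst-free.

What the generator does *not* emulate: motor-unit firing statistics, muscle
fatigue, electrode lift/shift artifacts, movement-artifact transients, or
inter-day electrode placement variance. Passing tests therefore demonstrate
the pipeline's correctness and its behaviour under controlled conditions,
not clinical performance on recorded falls.

## Preprocessing

sEMG is informative in roughly 10–500 Hz. `design_bandpass()` builds the
denoising filter as a cascade of a third-order Butterworth high-pass at
10 Hz and a third-order Butterworth low-pass at 500 Hz (18 dB/octave
roll-off), discretised by bilinear transform with pre-warping so the -3 dB
points sit exactly at the nominal cutoffs. There is no mains notch: the
emulated acquisition hardware shields power-line interference, and keeping
50 Hz preserves in-band signal; `generate_recording(mains_hz = 50)` exists
so the filter's (intentional) transparency at 50 Hz can be tested.

Application is a causal single pass by default, matching the on-line
framing of a fall alarm; `zero_phase = TRUE` applies each stage
forward-backward for off-line analysis (doubling the effective order, which
is why the 18 dB/octave figure is always measured on the single-pass
response). No padding is applied; analyses discard the first ~0.2 s
transient where it matters.

## Active-segment extraction

Movements occupy only part of each recording. The segmenter slides a
non-overlapping window of `n = 100` samples and computes the mean
short-term energy `Ek` (mean of squared samples). Multichannel recordings
are first combined by per-sample root-sum-of-squares — a symmetric rule
that responds to activity on any muscle (`combine_channels()`).

Static thresholds are calibrated, not guessed (`calibrate_thresholds()`):
from segmented calibration intervals, the mean ratio of onset-window (resp.
offset-window) energy to the interval's maximum energy is multiplied by the
maximum energy `Ek_max` of the held-out rest data, giving the onset
threshold STS and offset threshold STE. In this package the generator's
annotations stand in for manual segmentation: 20% of the recordings
(evenly spaced through the collection, so every gesture is represented)
supply the ratios, the rest supply `Ek_max`
(`calibrate_from_recordings()`). In the evaluation harness this calibration
uses training-fold subjects only.

Detection (`detect_segments()`): window `k` opens a segment when
`Ek > STS`, the mean of the previous `l` energies is below `Ek`, and the
mean of the next `m` energies is above STS; the segment closes at the first
later window with `Ek < STE` whose following `l` energies average below it.
The look-back count is tied to the sampling rate and window size by
`l = fs/(2n)` — 7.5 at the defaults, integerised to 8 by round-half-to-even
— and `m` must lie strictly between `fs/(2n)` and `fs/n`; the rounded
interval midpoint 11 is the default. Both are overridable. The prose rule
for the look-ahead is ambiguous between "mean of the next m windows above
STS" and "every one of them above STS"; the mean reading is the default and
`lookahead = "per_window"` selects the stricter variant.

Numerical conventions worth stating:

* **Sample mapping.** The rule operates on the coarse window grid
  (hop = n = 100 samples). Boundaries are mapped to samples by re-scanning
  +-n samples around the coarse boundary with a short n/4 energy window and
  placing the boundary at the threshold crossing; this removes the +-100
  sample grid quantisation while leaving the detection rule untouched.
  Passing `signal = NULL` to `detect_segments()` keeps pure window-grid
  output.
* **Degenerate inputs.** Quiet input returns an empty segment list (not an
  error); a plateau that never drops below STE runs to the end of the
  series; detections shorter than 0.3 s are discarded, since a sub-300 ms
  event cannot fill even one feature window.
* **Equivariance.** Scaling the signal by `c` scales every `Ek` by `c^2`;
  with thresholds recalibrated on the scaled data the segment boundaries
  are identical (tested).

## Features

Active segments are analysed in sliding windows of 300 samples (200 ms)
with a 150-sample step (100 ms) — short enough to keep classification
latency under the ~300 ms usability bound.

**Spectrograms (SPM).** Each frame is weighted by a Hamming window
(`(1-a) - a cos(2*pi*n/(N-1))`, `a = 0.46`), zero-padded to the next power
of two (512) and Fourier transformed; the magnitude bins inside 10–500 Hz
are retained and the per-channel spectrogram is min-max normalized to
[0, 1], making channels of different gain comparable. The Hamming taper's
first side lobe is ~44.6 dB below the main lobe at these parameters, which
is what keeps spectral leakage from smearing the band structure the
classifier relies on. The frequency axis is then reduced by PCA
(`fit_pca()`, `apply_pca()`) to `k = 8` orthonormal components, fit on
training-fold frames only and applied to held-out data. An explained-
variance table is reported by `variance_report()`; on synthetic frames the
8-component cumulative share is lower than on real recordings (broadband
noise carriers have flatter spectra), which affects nothing downstream.
The half-window spectrogram hop (150 samples) was chosen to coincide with
the feature-window step; a one-third-window hop is available through
`step`.

**Time-domain features.** `time_domain_features()` evaluates the six
classic myoelectric features per window and channel: MAV, population VAR,
WL, RMS, ZC and SSC. The zero-crossing dead-band defaults to
`0.01 x window RMS`, keeping the count invariant to the arbitrary amplitude
units of sEMG hardware; SSC is the mean slope-sign-change indicator over
interior points (so `SSC*(n-2)` is an integer count). All six are verified
against naive loop oracles to 1e-10.

## The classifier

`build_network()` constructs the dual-parallel-channel CNN on input tensors
of 8 frames x 8 components x 4 channels (the four muscles enter as input
depth, so the very first convolution mixes muscles and can exploit
co-contraction):

* **branch 1**: 2x4 kernels (2 time frames x 4 spectral components) —
  elongated along the component axis;
* **branch 2**: the transposed 4x2 kernels — elongated along time;
* each branch stacks three convolutions with 10, 20, 20 filters, ReLU, and
  2x2/stride-2 max pooling after the first two;
* the flattened branch outputs are concatenated into a fully connected head
  of 40, 10 and 4 units with ReLU and dropout 0.5 between the dense layers,
  ending in a softmax over the four gestures.

Ablations: `dpc1`/`dpc2` duplicate one branch (transposition preserves the
parameter count exactly — tested), and `single` is one branch of square 2x2
kernels. Published descriptions of such stacks leave pool geometry and
padding unstated; this implementation uses "same" zero padding (a valid
8x8 input would not survive three convolutions otherwise) and 2x2/stride-2
pooling with ceiling semantics on odd extents. Printed kernel triples like
"2 x 4 x 1" are read as spatial height x width, with the trailing number
describing the incoming feature-map depth, which is forced by the previous
layer rather than being a free hyperparameter.

The engine is written in base R arrays (im2col convolution, cached
forward/backward, inverted dropout, overflow-safe softmax paired with
categorical cross-entropy, Adam at learning rate 1e-3, batch size 32).
Analytic gradients are tested against central differences to better than
1e-4. Training (`cnn_train()`) draws a random mini-batch per iteration, is
bit-deterministic given its seed, and can hold out a validation fraction
for early stopping with best-epoch restoration (`val_frac`, `patience`);
the evaluation harness trains for a fixed 50 epochs with no split, which
keeps the LOSO grid deterministic and cheap. Dropout is inference-inert:
repeated predictions are identical.

Segments have variable duration, so a segment's frame axis is cut into
overlapping 8-frame blocks (step 4, tail-aligned so the segment end is
always covered; segments shorter than 8 frames are zero-padded into one
block). The network scores blocks; the segment-level probability vector is
the mean of its block probabilities and the prediction is its argmax.

Classical baselines (`baseline_classifier()`) wrap established
implementations — RBF-kernel SVM (e1071), LDA (MASS) and KNN (class) — on
per-segment summaries (per-feature mean and SD over frames; the maximum is
not used because per-channel min-max normalization pins it at 1).

## Evaluation

`loso_split()` builds one fold per subject. Per fold, `run_experiment()`
recalibrates segmentation thresholds and refits PCA on training subjects
only (a fingerprint test asserts that corrupting held-out data changes
neither), trains each requested method, and reports accuracy, sensitivity
and specificity in percent with falls positive:

* `Ac = (TP + TN) / (TP + FP + TN + FN) x 100`
* `Se = TP / (TP + FN) x 100` (fall detection rate)
* `Sp = TN / (FP + TN) x 100` (daily-activity detection rate)

Training is four-class; Se/Sp collapse the three daily activities into the
negative class and the full 4x4 confusion table is kept alongside. An
undefined ratio (no positives in a fold) is reported as `NA` with a
diagnostic, never as 0. Per-fold metrics, their means, and pooled-count
metrics are all reported; per-method wall-clock seconds are logged as
informational only, since they are hardware-dependent.

## Problem sizes and expected behaviour

The test suite and worked examples run desk-scale versions of the study
conditions, chosen once: module tests use 3 subjects x 4 reps (48
recordings); segmentation recovery is measured on 100 recordings
(5 subjects x 5 reps, easy setting), where at least 90% of annotated bursts
are recovered with both boundaries within 200 samples and burst-free
recordings yield at most 5% false alarms; the end-to-end LOSO experiment
uses 4 subjects x 5 reps with the dual-branch network trained 50 epochs,
reaching 100% mean LOSO accuracy on the easy setting (the separation
between synthetic classes is generous; the number demonstrates pipeline
correctness, not clinical performance). The full 10 x 10 condition runs
through the same code path (`pipeline_config()` defaults) in tens of
minutes on one CPU.

## Known limitations

* Synthetic recordings cannot certify performance on real falls; the
  headline numbers published for recorded datasets are not reproducible
  without those recordings, and this package does not attempt to match
  them.
* The static-threshold segmenter assumes the actions' energies are within
  roughly one order of magnitude; pooled calibration degrades gracefully
  but visibly as that spread grows (see the generator discussion above).
* The RMS feature mode carries little class information after amplitude
  normalization — deliberately so, since amplitude is subject- and
  hardware-dependent; it exists as the comparison arm, and spectrogram
  features dominate it in every configuration tested.
* The CNN engine is plain R: adequate for 8x8x4 inputs and hundreds of
  training blocks, not for large-scale use.
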