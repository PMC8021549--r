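---
title: "Methods: detecting true head impacts in mouthguard kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting true head impacts in mouthguard kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Instrumented mouthguards record head kinematics during contact sports: a
triaxial accelerometer (±400 g, 1000 Hz) and a triaxial gyroscope
(±4000 deg/s, 8000 Hz) ride on the upper dentition, and whenever any linear
acceleration component exceeds a 10 g trigger the onboard recorder stores
the 50 ms before and 150 ms after the crossing — a 6 × 200 window on a 1 kHz
grid. The catch is that chewing, biting and handling the device also cross
10 g, so a large fraction of stored events are not head impacts at all.
Classifying each stored window as a *true impact* or a *false event* —
without frame-by-frame video review — is the task this package addresses.

Two classifiers are implemented. The primary one is a family of four small
convolutional networks that consume the raw 6-channel window; the reference
study selected the fourth (two 1D convolution blocks fused into a 2D feature
image, one 2D convolution, global average pooling, softmax). The baseline is
the field's older recipe: hand-engineered features, greedy sequential
forward selection, and a soft-margin SVM.

## The synthetic data generator

The video-verified field recordings behind the original work are not public,
so the package ships a seeded simulator (`generate_dataset()`,
`simulate_session()`) that reproduces the *structure* of the task rather
than any particular dataset:

* **True impacts** are haversine linear-acceleration pulses
  (peak 12–100 g, base width 4–15 ms, random direction) with a coupled
  damped-sine angular-velocity transient (200–3000 deg/s about an orthogonal
  axis) and band-limited sensor noise (0.5 g / 2 deg/s). A short haversine
  is the standard idealization of an impact acceleration pulse, and
  rotation is what distinguishes a struck head from a struck device.
* **False events** come in three families: `CHEW` (a quasi-periodic
  raised-cosine train at a 1–3 Hz fundamental), `BITE_SPIKE` (a sub-2-ms
  spike with high-frequency ringing) and `HANDLING` (a broadband enveloped
  noise burst), each with deliberately weak angular coupling (peak angular
  velocity at most 0.2 × 10 deg/s per g of linear peak).
* Amplitude ranges of the two classes overlap (12–100 g vs 12.5–40 g), so
  amplitude alone cannot solve the task; waveform shape and rotational
  content must be learned. A property test verifies that two trivial
  features separate the classes at better than 80% — the synthetic task is
  learnable, but not degenerate.
* Because the device triggers per axis, a weak oblique impact whose largest
  axis component stays under 10 g would never be stored. The generator
  emulates this selection by redrawing directions until the dominant axis
  clears the threshold with margin; artifact amplitudes start at 12.5 g for
  the same reason (their fixed jaw-axis direction has a 0.94 dominant
  component).
* Group keys are assigned in blocks of at most 20 consecutive events to
  stand in for per-player recordings, so leakage-safe grouped splitting can
  be exercised.

What the simulator does **not** model: biofidelic skull dynamics, helmet
contact mechanics, real field amplitude distributions, or the long tail of
odd artifacts a season of football produces. Passing tests on synthetic data
demonstrate that the pipeline is implemented correctly and that the training
recipe works on a task of this structure — they are not evidence about
performance on real mouthguard data, whose published values this package
does not attempt to reproduce.

The default study conditions mirror the reference design: 358 true / 500
false events for development, 65/100 for out-of-sample checks.

## Trigger emulation

`detect_events()` scans the 1 kHz linear stream sample by sample: a trigger
fires at the first sample where any component exceeds the threshold in
absolute value, provided no trigger fired within the preceding refractory
interval (default 200 ms, one window length — the recorder cannot help but
re-cross threshold inside an oscillating transient, and the device stores
one window per event). The 8 kHz gyroscope stream is
anti-aliased with an 8-sample boxcar and decimated onto the 1 kHz grid so
that all six channels share the 200 columns; this makes the "1 × 200" window
statement literal for every channel. Windows that would extend past either
end of a trace are dropped rather than padded: the physical device buffers
continuously, so partial windows can only be simulation artifacts. The
window convention is half-open, [−50, +150) ms, with the trigger at 0-based
column 50; a brute-force per-sample oracle in the test suite checks the
emulator on 100 seeded random traces.

## Preprocessing

* **Augmentation** (`augment_time_shift()`): each training event yields 5
  copies shifted right by 1–5 samples (1 ms each at 1 kHz), with
  leading-edge padding. The pre-trigger region is near baseline, so the
  padding introduces no structure. Only integer-sample shifts are supported.
  Augmentation happens after splitting and only on the training partition,
  so shifted copies can never leak into evaluation.
* **Class weighting** (`compute_class_weights()`): `w_c = N / (2 N_c)`.
  Each example's loss is multiplied by its class weight, making the summed
  weight per class equal — the imbalanced classes are "equally treated" in
  the loss. At the study ratio this gives 858/716 ≈ 1.198 for impacts and
  0.858 for artifacts.
* **Normalization** (`normalize_events()`): per-channel z-scoring with
  statistics from the training partition only, stored on the model and
  re-applied at prediction. Raw-unit training is available by flag. The
  choice is conventional rather than prescribed; the networks train in
  either regime, but standardized inputs let one learning rate serve all
  four architectures.
* **Splitting** (`split_events()`): group-aware by default — whole
  recording groups are shuffled (seeded) and assigned greedily to
  train/validation/test until each partition's event quota is met, so no
  group spans partitions. Whether the original study split player-disjoint
  is not stated; group-awareness is the safer default and a flag disables
  it.

## The four architectures

All four stacks consume the 6 × 200 window (channels last internally). The
published descriptions are followed literally where they are precise:
filter counts, kernel lengths (a "5 × 1" filter is kernel length 5 along
time, applied across all input channels), pool size 2, dropout rates, batch
normalization placement, and the head activations — sigmoid heads (M1, M3)
trained with binary cross-entropy, softmax heads (M2, M4) with two-class
cross-entropy.

Two points were genuinely open:

* **The 1D→2D fusion in M3/M4** ("a reshaped 2D combination of layer one
  and layer 2"). The reading implemented: max-pool the first block's
  feature map along time to the second block's length (50), then stack the
  per-channel feature rows of both blocks into one single-channel image —
  192 × 50 for M4 (64 + 128 rows), 144 × 50 for M3 (48 + 96). This makes
  the "3 × 15 patch, 3 × 1 stride" literal and well-formed: the kernel
  spans 3 stacked feature rows per step (192/3 = 64 output rows for M4,
  144/3 = 48 for M3) and 15 ms of time. A "two-row image" reading (one row
  per block) founders on the blocks' unequal channel counts, which would
  need an ad-hoc projection before any 3-row patch could apply.
* **Padding**: "same" padding everywhere (floor/ceil split for even
  kernels), so 200-column inputs survive the two pool-by-2 stages at
  100 and 50 columns exactly.

Weight initialization is seeded Glorot-uniform; the optimizer is plain SGD
with momentum 0.9, learning rate 0.01, batch 32, 20 epochs, per-epoch
seeded shuffling, and no weight decay or schedule (none is described).
Decision threshold is 0.5 with ties called impacts — when the model is
exactly undecided, the costlier error is the missed impact.

### Numerical engine

No deep-learning framework is used: the layers, their backward passes and
the SGD loop are implemented in the package. Convolutions are lowered to an
im2col matrix product per batch (the 2D convolution, whose row stride
equals its kernel height, reduces exactly to a 1D convolution over a
reshaped tensor), and a compiled single-precision step
(`src/mignet_step.cpp`) executes the whole graph per batch — float32 is the
precision the mainstream frameworks train in, and it halves memory traffic.
Two independent checks pin the engine down: a double-precision R
implementation of every layer is kept as a reference (the compiled engine
must match its forward pass to 1e-5), and the reference's gradients are
checked against central finite differences. Batch-normalization uses
momentum 0.99 and epsilon 1e-3 on batch statistics, with running statistics
at inference; dropout masks draw from R's RNG so a seed fixes the entire
run.

One inference-consistency detail matters in M4, the only architecture that
combines dropout with batch normalization: dropout inflates train-time
activation variance by 1/(1−p), so running statistics accumulated during
training systematically mismatch the dropout-free activations seen at
inference (the dropout→batchnorm variance shift). After the last epoch the
package therefore re-estimates all batchnorm running statistics with one
dropout-free pass over the training data, accumulating an exact arithmetic
mean of batch statistics. Without this step the trained M4 classifies its
training distribution perfectly under batch statistics yet loses roughly
15 accuracy points under stale running statistics; with it, train-path and
inference-path distributions agree. The training recipe itself is
untouched.

## The SVM baseline

The feature set ("features_v1", 49 values) is versioned because the
original list is not enumerated: for each channel and each resultant, peak
absolute value, time to peak, mean power, threshold up-crossings (10 g
linear / 100 deg/s angular), spectral centroid, pre/post-trigger energy
ratio; plus the angular-to-linear energy ratio. Sequential forward
selection is re-implemented as greedy addition by 5-fold cross-validated
SVM misclassification (stratified seeded folds, ties to the lowest feature
index, stop on no improvement or `k_max`). The SVM itself is the standard
soft-margin implementation (`e1071`), RBF kernel and box constraint 1 by
default — the original's kernel is unstated — fit on features standardized
with training statistics. The selection criterion's monotone error path and
a brute-force subset search on a toy problem validate the greedy routine.

## Evaluation

`confusion()` tallies TP/FP/TN/FN with the true impact as the positive
class and derives sensitivity, specificity, accuracy, precision (PPV) and
NPV (= TN/(TN+FN); the published tables' NPV column is reproduced by this
standard formula). Zero-denominator ratios are `NA` with an explicit flag,
never silently zero. `format_confusion()` renders rates as integer percent
and predictive values to two decimals — the published tables' style, with
half-up rounding, which reproduces every printed cell from its printed
counts.

## Problem sizes and runtime

The end-to-end experiment (`impact_experiment()`) uses the study-sized
dataset: 858 events, group-aware 60/20/20 split, ×5 augmentation of the
training partition (≈3100 training windows), M4 for 20 epochs — about
five minutes on one CPU core — plus the SVM baseline (forward selection
over 49 features, ≈1 minute). Unit tests use much smaller configurations;
the deep end-to-end checks live in the acceptance tests and
`scripts/acceptance.R`.

## Known limitations

* Synthetic realism is unverifiable against the original data; the
  generator's waveform families are plausible but stylized, and real
  artifact diversity is certainly larger.
* The fusion reading in M3/M4, though argued for above, is one
  interpretation of an under-specified description; a different reading
  would change parameter counts.
* The published real-data performance (Table-style field results) is out of
  scope: those numbers depend on data that cannot be regenerated.
* The single-precision engine is deterministic per platform/BLAS but not
  guaranteed bit-identical across BLAS implementations.
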