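# mignet

Head-impact detection for instrumented-mouthguard kinematics.

Mouthguard sensors store a 6-channel kinematic window — triaxial linear
acceleration (g, 1000 Hz) and triaxial angular velocity (deg/s, decimated
from 8000 Hz) — whenever any linear-acceleration axis crosses a 10 g
trigger: 50 ms before to 150 ms after the crossing, 200 samples per
channel. Many stored events are not head impacts but chewing, biting or
handling artifacts that also cross the trigger. This package classifies
each stored window as a **true impact** or a **false event**, for
researchers studying head-impact biomechanics and mild traumatic brain
injury who need field recordings cleaned without frame-by-frame video
review.

It provides, end to end:

* **Domain types and I/O** — event tibbles with a 6 × 200 `samples`
  list-column; plain CSV exchange in a raw schema or a harmonized
  common-data-element (CDE-style) schema with a sidecar data dictionary
  (`read_events_csv()`, `write_events_csv()`).
* **Trigger emulation** — `detect_events()` reproduces the onboard
  recorder on continuous dual-rate traces: per-axis 10 g threshold, first
  crossing wins, refractory dead time, 50/150 ms pre/post windows, gyro
  boxcar-decimated 8 kHz → 1 kHz.
* **A seeded synthetic generator** — haversine impact pulses with coupled
  damped-sine rotation vs chew/bite/handling artifact waveforms, at the
  field-study class ratio (`generate_dataset()`, `simulate_session()`);
  the real video-verified recordings are not public.
* **Preprocessing** — 1–5 ms time-shift augmentation of training events,
  inverse-frequency class weights `w_c = N/(2 N_c)`, per-channel
  train-statistics standardization, leakage-safe grouped splits.
* **Four small convolutional networks** (`M1`–`M4`) trained by SGD
  (batch 32, 20 epochs, learning rate 0.01, momentum 0.9) with
  class-weighted cross-entropy; `M4` — two 1D convolution blocks fused
  into a 2D feature image, one 3 × 15 2D convolution, global average
  pooling, softmax — is the architecture of record. The layers and their
  backward passes are implemented in the package (R reference engine plus
  a compiled single-precision batch step); no deep-learning framework is
  required.
* **An SVM baseline** — 49 engineered features, greedy sequential forward
  selection by 5-fold cross-validated error, soft-margin SVM.
* **Evaluation** — `confusion()` with TP/FP/TN/FN, sensitivity
  `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, precision (PPV) and
  NPV, plus table-style rendering and model comparison.

## Worked example

```r
library(mignet)

# a labeled synthetic dataset at the study's class ratio
events <- generate_dataset(n_true = 358, n_false = 500, seed = 1)
dplyr::count(events, label)
#> # A tibble: 2 × 2
#>   label           n
#>   <chr>       <int>
#> 1 FALSE_EVENT   500
#> 2 TRUE_IMPACT   358

# leakage-safe split, augment the training partition only
parts <- split_events(events, split_spec(0.6, 0.2, group_aware = TRUE, seed = 2))
train <- augment_dataset(parts$train, n_copies = 5)

# class weights at the full-study ratio
compute_class_weights(events$label)
#> TRUE_IMPACT FALSE_EVENT
#>    1.198324    0.858000

# train the architecture of record and score the held-out test set
model <- train_mignet(build_mignet(mignet_config("M4", seed = 3)),
                      train, parts$val)
pred  <- predict(model, parts$test)
confusion(pred$pred_label, parts$test$label)
```

The one-call version of the same experiment (plus the SVM baseline on the
same split) is `impact_experiment(seed = 1)`; with seed 1 the held-out
test partition holds 160 events (57 impacts, 103 artifacts) and the two
classifiers print:

```
M4:  <confusion_metrics> n = 160 (TP 57, FP 0, TN 103, FN 0)
     sensitivity 100%, specificity 100%, accuracy 100%, PPV 1.00, NPV 1.00
SVM: <confusion_metrics> n = 160 (TP 56, FP 0, TN 103, FN 1)
     sensitivity 98%, specificity 100%, accuracy 99%, PPV 1.00, NPV 0.99
```

Sensitivity is the fraction of true head impacts recovered, specificity
the fraction of artifacts correctly discarded; PPV/NPV are the posterior
probabilities that a flagged/discarded event really is/is not an impact.

Published confusion tables can be re-derived directly from their counts:

```r
format_confusion(confusion(counts = c(tp = 38, fp = 6, tn = 409, fn = 12)))
#>      TP    FP    TN    FN Sensitivity Specificity Accuracy  PPV   NPV
#>      38     6   409    12         76%         99%      96% 0.86  0.97
```

## Scope

Synthetic data emulates the *structure* of the task, not any real
recording; published field-data performance is not reproduced here (the
underlying dataset is not public). See the methods vignette
(`vignettes/impact-detection-methods.Rmd`) for the model descriptions,
the design decisions taken where the published description is silent, and
the limitations of the simulator.
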