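---
title: "Recognising daily activities with stacked denoising autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising daily activities with stacked denoising autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wrist-worn inertial sensors — a tri-axial accelerometer (g) and a tri-axial
gyroscope (deg/s) — produce continuous six-channel streams from which daily
activities can be recognised. Sustained activities come in two flavours:
*static* postures (standing, sleeping, sitting in front of a TV) and
*dynamic*, rhythmic movements (walking, running, sweeping). The harder
targets are *transitional* activities — stand-to-sit, sit-to-stand,
stand-to-walk, walk-to-stand, lie-to-sit, sit-to-lie — which last a few
seconds rather than minutes. Because transitions are short, they contribute
far fewer training windows than sustained activities (roughly 5:1 here),
and a classifier trained on the raw distribution collapses onto the
majority classes. `sdaehar` implements the full pipeline that addresses
this: sliding-window segmentation, class rebalancing, and a stacked
denoising autoencoder (SDAE) classifier trained from scratch.

## Segmentation

A recording is cut by a sliding window of `window_size = 512` samples with
50% overlap (step 256). At the default 102.4 Hz sampling rate a window is
exactly 5 s. Each window is flattened channel-block-wise —

\[
x = \{acc_x(1{:}n),\; acc_y(1{:}n),\; acc_z(1{:}n),\;
      gyr_x(1{:}n),\; gyr_y(1{:}n),\; gyr_z(1{:}n)\}, \qquad n = 512,
\]

giving instances of length \(M = 6n = 3072\). Trailing samples that do not
fill a window are discarded; windows never span recordings, so no instance
mixes two bouts or two subjects. The step is `round(window * (1 -
overlap))` with half-away-from-zero rounding, and window counts follow
\(\lfloor (N - w)/s \rfloor + 1\) for \(N \ge w\).

## Standardization

The classical per-feature recipe "subtract the mean, divide by the standard
deviation" does not by itself produce values in \([0, 1]\), yet the
autoencoder's cross-entropy reconstruction loss needs inputs in that range.
`fit_standardizer()` therefore z-scores each feature with training-set
statistics and then affinely rescales the z-values to \([0, 1]\) using the
training-set minimum and maximum of the z-scores. Validation and test
values falling outside the training range are clipped; a feature with zero
training variance maps to the midpoint 0.5. The transform is invertible on
training data (`invert_standardizer()`), which the tests exploit.

## Rebalancing

Three equalisation strategies are provided, all deterministic under a seed:

* **Random oversampling** duplicates uniformly chosen minority instances
  until every class reaches the largest class count.
* **Random undersampling** keeps a uniform without-replacement subset of
  each class at the smallest class count.
* **SMOTE** synthesises minority points: pick a class member \(x\), one of
  its \(k = 5\) nearest same-class neighbours \(x_n\) (Euclidean), and a
  single \(r \sim U[0, 1)\), and emit \(x + r\,(x_n - x)\).

The SMOTE update is sometimes written with the scalar Euclidean distance
\(\lvert x - x_n \rvert\) in place of the component-wise difference; read
literally that adds the same scalar to every coordinate and leaves the
segment between the parents. We default to the component-wise
interpolation, which is the construction the SMOTE literature defines and
keeps every synthetic point between its two parents (and hence inside the
class bounding box); the literal scalar form remains available as
`resample_plan(interpolation = "literal")` for fidelity experiments. One
shared \(r\) is drawn per synthetic point, not per component.

## The stacked denoising autoencoder

Each layer holds an encoder \(y = \sigma(W_1 x' + b_1)\) and a decoder
\(z = \sigma(W_2 y + b_2)\), both sigmoid. During pretraining the input is
corrupted by *masking noise*: every component is zeroed independently with
probability \(a\) (the denoising factor, default 0.5), and the
reconstruction is scored against the **clean** input with summed binary
cross-entropy

\[
L(x, z) = -\sum_i \big( x_i \log z_i + (1 - x_i) \log (1 - z_i) \big),
\]

with \(z\) clipped to \([10^{-12}, 1 - 10^{-12}]\) so the logs stay finite.
Layers are pretrained greedily: layer 1 on the standardized instances, each
later layer on the clean (uncorrupted) encodings of its predecessor's
inputs, with corruption re-drawn afresh for every mini-batch inside each
layer's own training. Fine-tuning appends a softmax head over the 12
classes and trains the encoder stack plus head — decoders frozen, no
corruption — by backpropagation on categorical cross-entropy.

Design choices the underlying description leaves open, and how they are
resolved here:

* **Initialisation**: uniform in \(\pm\sqrt{6/(d_{in} + d_{out})}\),
  biases zero, seeded — the standard choice for sigmoid stacks.
* **Optimiser**: plain mini-batch gradient descent (batch 64), no momentum
  or weight decay; one "iteration" is one full epoch over the training
  set.
* **Corruption scope**: masking is applied at every layer's own
  pretraining, not only at the raw input.
* **Fine-tuning scope**: decoder parameters receive no gradient; the
  fine-tuned network is exactly an MLP of the encoders plus the head.
* **Loss pairing**: softmax + categorical cross-entropy, the canonical
  pairing for a probabilistic classification head.

All gradients are computed analytically in matrix form; the test suite
checks them against central finite differences (relative error below
\(10^{-5}\)) and checks that zero corruption reproduces, update for update,
an independently written plain autoencoder trainer.

### Reference hyperparameters

| parameter | default | unit / note |
|---|---|---|
| hidden layers | 2 × 500 units | `train_config(hidden_sizes=)` |
| denoising factor \(a\) | 0.5 | masking probability |
| pretraining rate | \(10^{-7}\) | per mini-batch GD step |
| fine-tuning rate | 0.01 | per mini-batch GD step |
| epochs | 200 | both phases |
| batch size | 64 | instances |
| window | 512 samples (5 s) | 50% overlap |
| split | 6:2:2 | train/validation/test |

With plain gradient descent the product of learning rate and epoch count
is what fixes how far training travels, so shorter budgets need
proportionally larger rates. The packaged end-to-end checks and the
acceptance script run the default study at a reduced budget — 3
pretraining epochs per layer and 25 fine-tuning epochs at a fine-tuning
rate of 0.5 — which converges on the synthetic task in a few minutes of
CPU time while exercising every stage at full scale (10 subjects, ~8,600
windows of 3,072 features, 14,400 after oversampling).

## The synthetic study

No public recording set accompanies the package, so `generate_study()`
fabricates one. The generator is a statistical stand-in, not a
biomechanical simulator; its defaults encode one fixed protocol:

* **10 subjects**, sampling at **102.4 Hz**, master seed spawning one
  child seed per (subject, activity, repeat) so studies of any size are
  reproducible piecewise.
* **Static** activities: per-channel posture offset (gravity on one
  accelerometer axis: standing \((0,0,1)\) g, lying \((1,0,0)\) g, sitting
  \((0,0.6,0.8)\) g) plus Gaussian noise; one 300 s bout per subject.
* **Dynamic** activities: posture offset plus a class-specific sinusoid
  (walking 2.0 Hz, running 2.8 Hz, sweeping 0.9 Hz, with per-channel
  amplitudes and a random common phase) plus noise; one 300 s bout.
* **Transitional** activities: hold–ramp–hold bouts of 8 s (2.5 s start
  posture, logistic ramp over 3 s — a realistic postural-transition
  duration — then 2.5 s end posture), 12 bouts per subject. The logistic
  ramp is the simplest smooth monotone transition; holds are kept short so
  every 5 s window overlaps part of the ramp and no transitional window
  degenerates into a pure posture mislabelled as a transition.

Under the default windowing this yields 119 windows per continuous bout
and 2 per transitional bout: about 1,190 vs 240 instances per class over
10 subjects, the ~5:1 imbalance the rebalancing stage exists to fix. Noise
scales order the groups so per-window variance ranks static <
transitional plateau < dynamic, which the suite verifies over seeds.

What the generator deliberately does **not** model: inter-subject
variability beyond seed noise, sensor bias/drift and saturation, gravity
reorientation during movement, non-stationary gait, fatigue, or
mislabelled bouts. Passing the end-to-end check therefore demonstrates
that the pipeline's machinery — segmentation bookkeeping, rebalancing,
standardization, gradient-based training, evaluation — is correct and
well-coupled, not that the classifier would reach comparable accuracy on
field recordings.

## Stage ordering and leakage

The default `mode = "paper"` order is: segment → rebalance the whole
instance set → standardize (statistics from the whole set) → split 6:2:2.
Rebalancing before splitting lets duplicated (or interpolated) minority
instances land on both sides of the split, and fitting the standardizer on
everything leaks test statistics into training; both inflate test
accuracy. Since overlapping windows already share half their samples,
even a split of un-resampled windows is not subject-independent. The
alternative `mode = "leakfree"` splits first, rebalances and fits the
standardizer on the training portion only, and records the ordering in the
run manifest. The default reproduces the classical pipeline; the
alternative is the sound practice we recommend for any real comparison.

## Numerical conventions

* All stochastic stages (generation, corruption, shuffling, resampling,
  splitting, initialisation) flow from explicit integer seeds; child seeds
  are derived by a multiply–add hash modulo \(2^{31}-1\), so results are
  identical across platforms and session RNG state is always restored.
* Softmax is computed with the row-max subtracted; argmax ties break
  toward the lowest class index.
* Per-class metrics are reported in percent; zero denominators yield 0
  with a warning, and the per-class "accuracy" column repeats recall, the
  convention of activity-recognition result tables. Micro averaging makes
  precision = recall = accuracy identically for single-label multiclass
  prediction — a useful internal consistency check, verified on random
  confusion matrices.
* Models serialise to a single file: one JSON header line (format
  version, shapes, config, class order) followed by little-endian float64
  parameter blocks; the loader validates the dimension chain.

## Known limitations

* Plain gradient descent is deliberate (it keeps the training loop
  auditable) but slow at the reference learning rates; expect to trade
  epochs against rate as described above.
* SMOTE computes a full within-class distance matrix, which is quadratic
  in class size — fine at the ~1,200-instance scale, wasteful beyond.
* The `mode = "paper"` pipeline is reproduced as specified, leakage
  included; use `leakfree` for honest generalisation estimates.
* The synthetic generator's classes are separable by construction;
  real-world confusions (e.g. walking vs sweeping) are only weakly
  represented.
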