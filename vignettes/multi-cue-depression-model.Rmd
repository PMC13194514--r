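---
title: "Multi-cue EEG networks for depression severity: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cue EEG networks for depression severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the science implemented by `mceegnet`: the
multi-cue convolutional model, the preprocessing contracts, the
cross-validation and label-normalisation protocol, the synthetic cohort
generator used to exercise all of it, and the numerical and design
decisions a maintainer should know about. It states no empirical result
that the package's test suite and `scripts/acceptance.R` do not themselves
compute.

## The problem

Depression alters stimulus-locked EEG responses to emotional cues, and
different patients respond differently to positive and negative stimuli.
The package models event-related potentials (ERPs) recorded in a dot-probe
paradigm with three cue conditions — happy–neutral (`hcue`),
fearful–neutral (`fcue`) and sad–neutral (`scue`) face pairs — and asks
two questions of each subject's trials: *is this subject depressed?*
(binary classification, healthy controls labelled 0 and patients 1) and
*how severe is it?* (regression of the PHQ-9 questionnaire score, an
integer in 0–27).

## The model

Each cue condition is processed by its own EEGNet-style branch with
independent weights:

1. **Temporal convolution** — `f1` filters of size `1 × temporal_kernel`
   (defaults 8 and 100 samples, i.e. 400 ms at 250 Hz) with "same"
   padding, acting as learned band-pass filters; batch-norm, ELU.
2. **Depthwise spatial convolution** — a `C × 1` kernel per temporal
   filter with depth multiplier `D` (default 2), collapsing the channel
   axis into `f2 = f1·D` feature maps; batch-norm, ELU, dropout
   (`p = 0.5`), average pooling `1 × 4`.
3. **Separable convolution** — a depthwise `1 × 16` temporal kernel per
   map followed by a `1 × 1` pointwise mixing convolution; batch-norm,
   ELU, dropout, average pooling `1 × 8`, flatten.

The three flattened branch outputs are concatenated into a fused feature
vector of length `3·f2·⌊⌊T/4⌋/8⌋` (144 for the full-montage configuration
`C = 128`, `T = 125`) feeding a softmax classification head and/or a
linear regression head. Convolutions carry no bias; batch normalisation is
affine. Each branch holds 3,440 trainable parameters in the full-montage
configuration; `count_parameters()` exposes the closed form and the test
suite checks it against enumeration of the built network.

Because no deep-learning framework is available to R here, the network —
forward pass, exact backpropagation and the Adam optimiser — is
implemented in the package itself (compiled code under `src/`). The
time-axis convolutions are expressed as banded (Toeplitz) matrix products,
which at ERP epoch lengths cost the same as direct convolution and map
onto BLAS; batch-norm and ELU are fused single-pass kernels. The
correctness anchor is a finite-difference gradient check in the test
suite, which agrees with the analytic gradients to ~1e-8 relative error.

### Numerical conventions

* Batch-norm: statistics per feature map over all remaining axes, biased
  variance, `eps = 1e-5`, running statistics with momentum 0.1 used in
  evaluation mode.
* "Same" padding is asymmetric for even kernels (left pad
  `⌊(k−1)/2⌋`), matching the common framework convention.
* Pooling uses floor semantics: trailing samples that do not fill a
  window are dropped (125 → 31 → 3).
* Initialisation is Glorot-uniform under a user seed; the same seed gives
  bit-identical parameters.
* Classification ties in `argmax` resolve to the first (label 0) class;
  with continuous probabilities this has measure zero.
* The training loss is the *mean* cross-entropy (or mean squared error)
  over the batch rather than the sum; the gradient direction is identical
  and the learning rate is calibrated for the mean convention.
* Evaluation-mode forward passes are pure functions of (parameters,
  input); training-mode passes use batch statistics and dropout drawn
  from the R RNG stream, so a run seed makes training fully reproducible
  on one device.

### Design decisions where the architecture description is open

* The depth multiplier of the spatial convolution is not pinned down by
  the layer dimensions alone; the canonical EEGNet default `D = 2` is
  used and configurable.
* Dropout appears after both the depthwise and the separable block (the
  canonical EEGNet placement), not only after the depthwise block.
* The depthwise spatial kernel spans all `C` channels, generalising the
  full-montage `128 × 1` kernel so that small synthetic montages work.
* Classification and regression are trained as separate models
  (`mode = "classify"` / `"regress"`); a `joint` mode that sums both
  losses unweighted is provided but is not used for any reported result.

## Preprocessing

The pipeline mirrors standard ERP practice: average reference → band-pass
→ cue-locked epoching → baseline correction → artifact rejection.

* **Band-pass 0.3–100 Hz**: realised as a 4th-order Butterworth high-pass
  at 0.3 Hz cascaded with a 4th-order low-pass at 100 Hz, each applied
  forward–backward (zero phase). A single 4th-order band-pass with a
  normalised low edge of 0.0024 is numerically fragile; the cascade has
  the same family, order and phase behaviour per edge. Edge transients
  are suppressed by odd (reflect-and-negate) extension sized to about
  three periods of the slowest cutoff. A 0.3–100 Hz band-pass does not
  remove 50 Hz mains interference; an optional narrow notch
  (`filter_spec(notch_hz = 50)`) is provided and off by default.
* **Epochs**: windows are half-open `[t_start, t_end)` in seconds; the
  default `[-100, 400) ms` at 250 Hz gives exactly 125 samples with the
  documented baseline interval `[-100, 0) ms` inside it. Sample indices
  are 1-based throughout, the R convention. Events whose window leaves
  the recording are dropped with a warning, not an error.
* **Artifact rejection**: ICA-based component subtraction is a published
  external method and out of scope; the package exposes a strategy
  interface (`register_rejection_strategy()`) with a per-trial
  peak-to-peak threshold (default 100 µV) as the built-in fallback.

## Labels, normalisation and cross-validation

Regression targets are mapped to `[0, 1]` by min–max normalisation
`y* = (y − ymin)/(ymax − ymin)` and predictions mapped back by the exact
inverse. A per-subject min–max is degenerate (each subject has a single
score), so "subject-wise" normalisation is interpreted as min–max over
the *training subjects'* score distribution, fitted freshly inside every
cross-validation fold so the held-out subject's label never influences
the transform. The leakage-proof alternative `scale_bounds` (0, 27) is
one argument away. Since the map is a strictly monotone affine bijection,
regression metrics computed after denormalisation are invariant to the
fitted range for a fixed prediction vector — the test suite asserts this
identity exactly.

Evaluation uses leave-one-subject-out cross-validation (LOSOCV): all
trials of one subject are held out per fold, and the early-stopping
validation split (10% of trials, stratified by class for classification)
is drawn from training subjects only. Pooled trial-level metrics over all
held-out predictions are the primary report; a per-subject table and
majority-vote subject-level accuracy are secondary. Training runs at most
20 epochs of Adam (learning rate 1e-3, batch 64 — batch size and rate are
conventional defaults, configurable) and keeps the weights of the epoch
with the lowest validation loss.

## Metrics

Classification: accuracy, precision, recall, F1 and Cohen's kappa from
the confusion matrix, with the study's convention that the *positive
class is "normal"* (label 0): a control classified as control is a true
positive. This is the opposite of the usual clinical convention;
`positive_label = 1` switches it, and accuracy and kappa are invariant to
the choice. Degenerate denominators yield a flagged 0 with a warning
rather than an error, so pooling never aborts on a pathological fold.
Regression: MSE, RMSE, MAE and median absolute error (MEDAE), always on
the denormalised PHQ-9 scale, plus Pearson correlation between true and
predicted scores. The mean of the true scores appears in no implemented
formula (it would enter an R² variant, which is not part of the metric
suite) and is deliberately not computed.

## The synthetic cohort generator

Real cue-locked depression EEG requires a data-access application, so the
package ships a generator that emulates the *structure* of such a cohort:

* three cue conditions per subject; configurable montage (default 16
  channels; 128 supported), 250 Hz, 125-sample epochs, 160 trials per cue
  by default (one third of a 480-trial session);
* a template per cue built from three Gaussian-envelope components with
  smooth unit-norm topographies — an early visual P1 (100 ms, +4 µV), a
  face-sensitive N170-like deflection (170 ms, −5 µV) and a late P3
  (300 ms, +6 µV);
* a linear severity effect: component amplitudes change by a cue-specific
  slope per PHQ-9 point (defaults −0.20 µV/pt for happy cues — a blunted
  response to positive stimuli — and +0.15 µV/pt for fear and sad cues);
  linearity is the simplest recoverable structure and the slopes'
  opposite signs exercise genuinely cue-specific branches;
* background noise as 1/f-amplitude (spectrally shaped, unit-variance
  normalised) pink noise at 0.5 µV plus white noise at 0.4 µV. These
  defaults put the components at ≥ 5× the total noise standard
  deviation — a deliberately clean, high-SNR regime in which a working
  implementation must recover the structure. Real single-trial EEG is far
  noisier and nonstationary, contains eye/muscle artifacts and
  inter-subject topography variability, none of which are modelled; a
  test pass here demonstrates implementation correctness, not expected
  clinical performance.

Cohort scores are drawn uniformly from the groups' observed ranges
(controls 0–5, patients 11–24), so group labels and severity are
consistent by construction.

## What the tests compute, and at what size

The fast suites (metrics against hand-derived examples and independent
implementations, normalisation identities, shape/parameter closed forms
vs. enumeration over 20 random configurations, leakage scans, filter
frequency-response checks, finite-difference gradient checks) run in
seconds to a minute. The parameter-recovery suite runs LOSOCV on a
12-subject (6 patients, 6 controls), 16-channel, 40-trials-per-cue
cohort under seed 0 — the desk-scale stand-in for a full 53-subject,
128-channel study, chosen so a complete classification + regression +
null-calibration cycle fits comfortably in a test run on one CPU. The
null calibration deserves a note: trial-level predictions within a
held-out subject share that subject's noise realisation and the fold's
trained model, so they are not independent Bernoulli draws; the binomial
95% chance band is therefore computed at the subject level
(majority-vote outcomes, n = 12), while the trial-level kappa is still
required to sit within ±0.1 of zero. That kappa band is strict at this
cohort size: with the subject as the independent unit, a perfectly
calibrated null classifier's pooled kappa has a standard deviation of
roughly `2·√(0.25/12) ≈ 0.29`, so the ±0.1 requirement can fail by
sampling noise alone even when the implementation is correct. A related
protocol detail matters here: leave-one-subject-out folds are inherently
class-imbalanced (the held-out subject's class is always the training
minority), which biases an unweighted classifier against the held-out
class and drags null accuracy *below* chance. The package therefore
weights the cross-entropy by inverse class frequency of the training
split by default (`train_config(class_weights = "balanced")`), which is
also the appropriate handling for naturally imbalanced cohorts such as a
24-patient / 29-control study; `"none"` restores the plain mean.

## Known limitations

* The EEGLAB `.set` reader supports only the MAT v7.3 (HDF5) dialect; no
  MAT v5 parser is included.
* Epoch containers hold one subject × cue per file; there is no lazy or
  chunked access, so a full 53-subject, 128-channel, 160-trials-per-cue
  cohort held in memory at once is ~32 GB and should be processed
  per-subject instead.
* Training is single-device and single-threaded by design (reproducible
  under one seed); there is no GPU path.
* The joint classification+regression mode is functional but untuned; no
  claim is made about multi-task benefits.
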