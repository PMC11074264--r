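---
title: "Convolutional fuzzy neural networks for EEG emotion decoding: models and methods"
author: "fuzzyEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional fuzzy neural networks for EEG emotion decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyEEG)
```

## The problem

Affective state is commonly described by two continuous dimensions —
valence (how pleasant) and arousal (how intense) — rated by subjects on a
1–9 Likert scale while multichannel EEG is recorded in fixed-length trials.
The decoding task treated here is binary: is a trial's rating on one
dimension *high* (≥ a threshold, default 5) or *low*? The package
implements the full pipeline: band-power feature extraction, a hybrid
convolutional/fuzzy classifier, and split-based evaluation, all testable on
synthetic recordings that emulate the trials × channels × samples layout of
standard affective-EEG corpora (40 trials of 32+ channels resampled to
128 Hz, with four ratings per trial in the order valence, arousal,
dominance, liking).

## Feature extraction

Each trial is cut into windows of `windowSize` samples advancing by `step`
(default `windowSize/2`, 50% overlap; windows never span trial
boundaries). Each channel window is transformed with a two-sided DFT and
summarized by the mean of $|X_k|^2$ over the bins in each of five bands:
theta 4–8, alpha 8–12, lower beta 12–16, upper beta 16–25, gamma 25–45 Hz.
Band intervals are half-open $[lo, hi)$ so the shared printed edges (8, 12,
16, 25 Hz) are never counted twice. Features are ordered channel-major /
band-minor, and each window inherits its trial's binarized labels. The
result is a `FeatureMatrix`, a `SummarizedExperiment` whose columns are
windows.

Three numerical choices matter:

* **Zero padding.** Window sizes are in samples, and the conventional
  sweep reaches down to 4 samples; at 128 Hz a 4-sample window has 32-Hz
  bin spacing and most bands would contain no bin. Spectra are therefore
  zero-padded to `minFFTLen` (default 256 samples, i.e. 0.5-Hz bins)
  before band binning, which interpolates the spectrum without adding
  information.
* **Single-window periodogram.** No taper is applied; the estimator is the
  plain $|X_k|^2$ of the rectangular window. Off-bin sinusoids therefore
  leak energy into neighbouring bands; the synthetic-data tests account
  for this by comparing band means rather than extremes.
* **Binarization.** Label = high iff rating ≥ threshold; the threshold
  (default 5.0) is exposed because published work rarely states its cut.
  The positive class is "high" for both dimensions.

A 14-channel analysis subset (`defaultChannelSelection()`: channels 1, 2,
3, 4, 6, 11, 13, 17, 19, 20, 21, 25, 29, 31) is provided; with the five
bands it yields the canonical 70-dimensional feature vector. An optional
band-pass pre-filter is deliberately *not* applied: the corpora this
mirrors are distributed already filtered, and the band binning itself
discards out-of-band content.

## The CFNN

The classifier (built by `buildModel()`, defaults in `cfnnConfig()`):

| layer | output | parameters |
|---|---|---|
| Conv1D, 64 filters, kernel 5, same, ReLU | (73, 64) | 384 |
| Conv1D, 32 filters, kernel 3, same, ReLU | (73, 32) | 6176 |
| MaxPool width 2 (floor) | (36, 32) | 0 |
| Flatten | 1152 | 0 |
| Fuzzify, 2 rules | 2 | 4608 |
| BatchNorm | 2 | 8 (4 non-trainable) |
| Dense 2, softplus | 2 | 6 |
| Defuzzify | 2 | 4 |
| Softmax | 2 | 0 |

Totals: 11,186 / 11,182 trainable / 4 non-trainable. The kernels are
genuinely 1-D (length 5 and 3): the printed conv1 count 384 = 64·5 + 64
admits no 2-D reading. The 73-sample input width with same padding and
floor pooling is what reconciles the flatten width 1152 = 36·32. Extracted
feature tables are 70-wide; the model right-pads them with zeros to 73
(`padFeatures`), a stand-in for the unexplained 3 extra input columns of
the reference architecture.

**Fuzzification.** Every flattened feature $u_i$ has, per rule $j$, a
Gaussian membership $\exp\{-(u_i - m_{ij})^2 / 2\sigma_{ij}^2\}$ (the
singleton reading of fuzzifying a crisp input: the membership evaluated at
the observed value). The printed form of this membership in the source
literature omits the square on $(u - m)$; a Gaussian requires it and the
squared form is implemented. Aggregating 1152 memberships per rule by
their raw product underflows catastrophically, so the default is the
**geometric mean** $\exp(-e_j/n)$ of the degrees, where
$e_j = \sum_i (u_i - m_{ij})^2/2\sigma_{ij}^2$; it preserves the (0,1]
range, the ordering of rules, and differentiability, and the following
batch-norm absorbs the scale change. A max-shifted log-domain product
(`aggregation = "product-log"`) is available as an alternative. Standard
deviations are reparameterized through a softplus with floor
$\sigma_{\min} = 10^{-3}$, so positivity never needs clipping.

**Defuzzification.** Crisp outputs are the centre-of-gravity
$\nu_k = \sum_j C_{kj} x_j / (\sum_j x_j + \varepsilon)$ with
$\varepsilon = 10^{-9}$. The operator is defined for nonnegative
activations — for signed input its denominator can cross zero and the
output explodes. The dense layer before it therefore carries a **softplus**
activation: strictly positive outputs keep the denominator well-posed, and
unlike a hard ReLU the 2-unit bottleneck cannot die (a ReLU variant showed
seed-dependent collapse where both units clamped to zero, freezing the
model at chance). The final activation is a softmax trained with
categorical cross-entropy; one model is trained per emotion dimension.

**Batch normalization** uses batch statistics during training and moving
averages (momentum 0.9) in evaluation. Because the fuzzify strengths have
small variance and a training run may take only a few hundred optimizer
steps, the moving averages are additionally **recalibrated** after training
to the exact training-set statistics under the final weights; without this
the evaluation-mode scale can lag the training-mode scale by orders of
magnitude.

**Optimization** is Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷) at learning rate
0.01, batch size 256, for exactly 100 epochs — no early stopping or
schedules. A global gradient-norm clip (default 5) guards against the
transient spikes the defuzzification quotient can produce early in
training; it never binds near convergence. Inputs are standardized
column-wise on the training split (constant columns get unit scale), and
the stored mean/scale travel with the model. Initialization: Glorot
uniform for conv/dense weights, fuzzy means $\mathcal{N}(0,1)$ over the
standardized activations, sigmas 1, defuzzification centres
$\mathcal{N}(0, 0.1)$ — all from the config seed, so identical configs
build identical models and identical seeds reproduce training histories
bit for bit.

All gradients are hand-derived; `checkGradients()` verifies the fuzzy
operators against central finite differences (deviations ~10⁻¹⁰ on random
instances, tolerance 10⁻⁴), and the test-suite repeats the check through
the entire assembled network.

## Synthetic data

`generateDataset()` emulates the affective-EEG layout with a controlled
spectral contrast: each trial's class (low/high, assigned per dimension)
selects a profile of per-band amplitude gains; each channel is a sum of
three random-frequency, random-phase sinusoids per band scaled by those
gains, over pink (1/f-power) noise produced by spectral shaping of white
noise. Frequency and phase draws are independent of the gain values, so
raising one band's gain provably raises only that band's power. Ratings
are drawn uniformly from the open interval on the class's side of the
threshold, making binarization exactly invertible. Defaults — 8 trials,
16 channels, 8 s at 128 Hz, alpha-dominant "low" vs gamma-dominant "high"
profiles (the high-frequency band as the discriminative one), noise SD 0.5
against band gains 1.5 — run the full pipeline in seconds.

What the generator does *not* emulate: ocular/muscle artifacts, channel
covariance structure, non-stationarity within trials, inter-subject
variability, or any genuine relationship between spectra and affect.
Passing tests therefore demonstrate that the implementation recovers a
known spectral class structure end to end — not that the architecture
reaches any particular accuracy on real recordings.

## Evaluation

`confusionCounts()`/`classifierMetrics()` give accuracy, precision, recall
and F1 with the high class positive; zero-denominator metrics are reported
as 0 and flagged rather than erroring. Hold-out splits are stratified by
the binarized label with largest-remainder rounding (75:25 of 100 examples
gives exactly 75/25); k-fold partitions deal each class round-robin with a
rotating offset so fold sizes differ by at most one overall and within
class. Confidence intervals on accuracy are the binomial normal
approximation $\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$ clipped to [0,1] —
the narrow intervals typical of published tables are consistent with this
choice, and no resampling protocol is invented. K-fold experiments report
unweighted means over folds; splits are pooled across trials (windows of
one trial may land on both sides), with subject-grouped splitting left as
an extension. Reports carry seed, protocol and a config hash, and are
byte-identical across reruns.

## Problem sizes

The shipped tests and the acceptance script use 24-trial, 16-channel, 8-s
recordings (360 windows of 70 features at window 128/step 64) for the
end-to-end recovery and null-control experiments, and reduced
architectures for gradient and determinism checks; these sizes exercise
every code path while keeping a full run of the suite in a few minutes on
one CPU. Scaling to corpus-sized inputs (tens of thousands of windows) is
a matter of runtime, not of code paths.

## Known limitations

* The conv/batch-norm/Adam stack is written in R matrix algebra for
  inspectability, not speed; expect minutes, not seconds, for
  corpus-scale training.
* Only binary decoding per dimension; no multiclass head.
* The native on-disk dialects are R serialization and a plain-text
  directory; readers for the original binary distribution formats of
  public corpora are out of scope.
* Windows from the same trial can appear in both sides of a pooled split;
  with strongly autocorrelated real data this inflates hold-out accuracy,
  one reason the synthetic results say nothing about real-data accuracy.
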