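---
title: "Glaucoma classification with hybrid-attention NF-ResNets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glaucoma classification with hybrid-attention NF-ResNets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusnet)
```

## The problem and the model

Glaucoma screening from fundus photographs is a binary image-classification
task (normal vs glaucomatous eye). The structural signature a grader looks
for is the enlargement of the optic cup relative to the optic disc; a
cup-to-disc ratio (CDR) above 0.6 is conventionally treated as suspicious.
`fundusnet` implements a classifier built from three pieces:

1. **A normalization-free ResNet (NF-ResNet) backbone.** A bottleneck
   residual network (depths 26/50/101, layouts `[2,2,2,2]`, `[3,4,6,3]`,
   `[3,4,23,3]`) with *no* normalization layers. Stability is obtained
   instead from:
   * *scaled weight standardization*: every convolution uses the
     re-parameterized kernel \(\hat W = g \, (W - \mu) / \sqrt{N\sigma^2 +
     \epsilon}\) per output channel, where \(N\) is the fan-in, \(g\) a
     learnable per-channel gain, and \(\epsilon = 10^{-4}\) guards
     zero-variance kernels;
   * *variance-preserving activations*: ReLUs are scaled by
     \(\gamma = 1/\mathrm{sd}(\mathrm{relu}(Z))=\sqrt{2/(1-1/\pi)}\approx 1.7139\);
   * *analytic residual scaling*: block \(l\) computes
     \(x_{l+1} = x_l + \alpha f(x_l/\beta_l)\) with \(\alpha = 0.2\) and
     \(\beta_l\) the expected signal standard deviation, which grows by
     \(\alpha^2\) per block and resets at each downsampling transition
     (where the shortcut also consumes the activated, \(\beta\)-scaled
     input).
   A batch-normalized post-activation ResNet of the same topology is kept as
   the baseline and as a negative control: its training-mode features depend
   on batch composition, the NF family's provably do not.
2. **A hybrid attention block** applied to the final feature map
   \(X \in \mathbb{R}^{C\times H\times W}\):
   a pointwise convolution (bias, no nonlinearity) first reduces \(C\) to
   \(C' = C/r\). A *channel* branch pools the reduced map over space (mean
   and max), passes both descriptors through one shared bottleneck MLP
   (\(W_0\!: C'\!\to\!\max(1, C'/r_2)\) with ReLU, then \(W_1\) back to
   \(C'\), no biases), sums and applies a sigmoid, giving one gate per
   channel. A *spatial* branch pools across channels (mean and max),
   convolves the two stacked maps with a \(7\times 7\) kernel (symmetric
   padding 3, preserving \(H\times W\)) and applies a sigmoid, giving one
   gate per pixel. The reduced map is multiplied by each gate and the two
   recalibrated branches are concatenated, channel branch first, to
   \(2C'\) channels.
3. **A classification head**: global average pooling to a \(2C'\)-vector
   (or \(C\) for baselines) and a fully connected layer to two logits
   (normal, glaucoma) under softmax cross-entropy. Two logits rather than a
   single sigmoid unit keeps the loss the stated cross-entropy and makes
   the Grad-CAM++ target class explicit.

The package is self-contained: it carries its own differentiable compute
core (im2col/GEMM convolution with analytic backward passes, max pooling,
batch normalization, weight-standardization gradients, Adam) in
RcppArmadillo rather than depending on a deep-learning framework, and
every backward pass is verified against central finite differences in the
test suite.

## Training recipe

`train_config()` defaults encode the reference recipe: 100 epochs, Adam
with first-moment decay 0.9 (the stated "momentum"; Adam has no classical
momentum, so the value is read as \(\beta_1\), with \(\beta_2\) left at the
conventional 0.999), peak learning rate \(5\times 10^{-5}\), a 5-epoch
linear warm-up from zero followed by cosine decay to zero, 224 px inputs,
and train-time augmentation: random area crop (scale 0.8–1.0, aspect 1),
horizontal flip (p = 0.5), and ±0.2 brightness/contrast/saturation jitter.
The warm-up shape (linear from zero) and the cosine floor (zero) are the
most common pairing for this scheduler; the schedule is evaluated once per
epoch at `lr_at(epoch / epochs)`, so the rate at the end of warm-up (epoch
5 of 100) is exactly the peak and the cosine midpoint is exactly half of
it. Batch size (default 32) is config-controlled. The evaluation path
applies only a bilinear resize; with crop scale fixed at 1 and flip/jitter
disabled the augmentation reduces exactly to that resize (a tested
identity). Checkpoint selection keeps the epoch with the highest validation
accuracy, ties resolved to the earlier epoch; no class reweighting is
applied. Inputs are standardized as \((x - 0.5)/0.25\) before the stem.

## Split protocols

* `patient_level_split()` allocates 70% of *patients* to a training pool
  and 30% to the test set, then moves 20% of the pool to validation; both
  eyes of a patient always land in the same partition.
* `make_cv_folds()` + `cv_iteration()` implement the multi-dataset five-fold
  protocol: folds are assigned independently inside every (dataset, class)
  cell (grouped by patient when identifiers exist; largest-first greedy
  keeps cell fold sizes within one unit), the held-out fold of every
  dataset forms the test set, and the remaining records are split 80/20
  into training and validation, stratified per (dataset, class) cell — the
  strictest reading of "preserving class balance". Fold indices are
  reported 1-based, the R convention.
* All split operations are pure functions of (records, parameters, seed).

## Metrics

Glaucoma is the positive class (sensitivity = disease recall). F1 is
reported for the positive class, with the negative-class F1 also emitted,
since published tables in this area are sometimes ambiguous about the
reference class. Kappa is unweighted Cohen's kappa. Ratios with zero
denominators are `NA`, never 0. AUC is the Mann–Whitney statistic (midranks
for ties), which the tests verify equals the trapezoidal area under the
returned threshold-sweep curve; `pROC` serves as an independent
cross-check. Cross-validation results are pooled by summing confusion
counts and concatenating (label, score) pairs — the canonical aggregate —
with per-fold means also reported.

## The synthetic data generator

No public fundus data ships with the package; `generate_fundus()` renders
the *label-generating mechanism* instead: a reddish circular retina field,
a brighter slightly elliptical optic disc, a still brighter concentric cup
whose radius is CDR times the disc's geometric-mean radius (so
\(\sqrt{\text{cup area}/\text{disc area}}\) recovers the CDR exactly up to
pixelation — a tested oracle), vessels radiating from the disc, a
multiplicative illumination gradient, and additive Gaussian noise
(`noise_sigma` is a monotone SNR-degradation knob). The label is 1 iff
CDR > 0.6, with class CDRs drawn from U(0.2, 0.5) and U(0.65, 0.9), so the
task is solvable from the image alone — the property the learning test
relies on. Samples come as two eyes per patient (mirrored disc positions,
shared class), which is what makes patient-grouped splitting testable.
What the generator does *not* emulate: camera artifacts, pathology other
than cupping, label noise, co-registration problems, or the ambiguity of
real CDR grading near threshold (the class ranges deliberately leave a gap
around 0.6). Passing the learning test therefore shows the architecture
and recipe can extract a CDR-like relational feature end to end — not that
they reach any particular accuracy on clinical data.

## Desk-scale study sizes

`desk_benchmark()` is the package's scaled stand-in for the full training
protocol, chosen to be a faithful miniature: NF-ResNet-26 at width
multiplier 0.125 (a 256-channel final stage), 64 px inputs, hybrid
attention with r = 4, 800 synthetic images split by patient into
480 train / 120 validation / 200 test, batch 32, 5 warm-up epochs, 60
epochs total. The peak rate is 5e-4 rather than the reference 5e-5: the
reference schedule takes roughly two orders of magnitude more optimizer
steps, and Adam's total displacement budget (rate x steps) is what
transfers across scales, so the shorter schedule carries a proportionally
larger rate. Training history, held-out metrics and Grad-CAM++ maps are
all reproducible from one seed.

## Grad-CAM++

Heatmaps are taken from the concatenated attention output for attention
models and from the last convolutional features for baselines. With
\(g = \partial S/\partial A\) for class logit \(S\), the location weights
are \(\alpha = g^2 / (2g^2 + \sum_{ij} A_{ij}\, g^3)\) (the closed form
obtained when the class score is exponentiated), channel weights
\(w_k = \sum_{ij} \alpha\,\mathrm{relu}(g)\), and the map
\(\mathrm{relu}(\sum_k w_k A_k)\) is bilinearly upsampled to the input size
and min–max normalized. A zero gradient everywhere yields an all-zero map
with a warning. The toy single-convolution model with an analytically known
gradient is part of the test suite.

## Numerical choices and degenerate inputs

* Weight standardization uses the population variance and
  \(\epsilon = 10^{-4}\) added to \(N\sigma^2\); constant kernels
  standardize to zero.
* Max-pooling and the channel/spatial max descriptors break ties by first
  index (column-major), making every forward and backward pass
  deterministic.
* The channel-MLP hidden width is clamped to \(\max(1, \lfloor C'/r_2
  \rfloor)\) so small reduced widths never produce an empty layer.
* The attention block refuses channel counts not divisible by r with an
  error naming both numbers.
* Bilinear resizing uses the half-pixel-centre convention everywhere
  (augmentation, evaluation, heatmap upsampling).
* Non-finite training losses abort with a diagnostic rather than continuing.

## Design decisions that were genuinely open

* **r2 default 16** — the bottleneck ratio of the channel MLP follows the
  convention of the channel-attention literature; it is configurable and
  untuned here.
* **Concatenation order** — channel branch first; the head is
  order-sensitive, so the order is fixed and documented.
* **"2 × C′" output** — read as 2C′ concatenated channels (required for
  global average pooling to yield a flat vector).
* **No squeeze-excitation in the NF blocks** — some published NF variants
  include it; the backbones here do not, and the choice is visible in the
  builder.
* **Best-validation checkpoint** — which epoch's weights are evaluated was
  unstated; highest validation accuracy is used.
* **NF-ResNet-26 layout** — `[2,2,2,2]` bottleneck, the standard 26-layer
  convention.

## Known limitations

The compute core is single-threaded CPU code: full-width 224 px models run
(the shape tests include NF-ResNet-50 at width 1), but training at
reference scale is not practical here — conclusions about clinical-scale
accuracy cannot be drawn from this package's synthetic studies. The BN
baseline exists for architectural comparison and negative-control tests;
its training path is exercised at desk scale only. Checkpoints are R
serializations, not portable across deep-learning frameworks.
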