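---
title: "Multi-task self-supervised learning for endoscopic frame classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task self-supervised learning for endoscopic frame classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endossl)
```

## The problem and the approach

Labeled endoscopic video frames are scarce: annotating anatomical
landmarks (the Z-line, the esophageal body, the antrum/pylorus region)
requires expert review, while unlabeled frames are abundant.
`endossl` implements a multi-task self-supervised strategy for this
setting. Convolutional encoders are first pretrained on *pretext tasks*
whose labels are free — derived mechanically from the images themselves —
and the learned representations are then fused and fine-tuned into a
three-class landmark classifier.

Three pretext tasks are implemented:

* **Colorization.** The luminance image $I_L \in \mathbb{R}^{H\times W
  \times 1}$ (Rec. 601 luma, $0.299R + 0.587G + 0.114B$) is the input and
  the network reconstructs the color planes. The loss is the pixel-wise
  mean squared error between prediction and target, normalized by the
  total element count $H \cdot W \cdot C$. Two target modes exist: the
  default reconstructs the 3-channel RGB image (this is what the decoder's
  terminal 3-channel sigmoid produces), and an alternative predicts the
  two CIE Lab chrominance planes mapped affinely from $[-110, 110]$ into
  $[0,1]$. Both modes share the element-count normalization so their loss
  values are comparable.
* **Center-patch prediction.** The central patch $P_c$ ($p \times p
  \times C$) is replaced by a constant mid-gray fill (0.5 by default;
  configurable to the image mean) and the network reconstructs it from
  the surrounding context. The loss is the MSE over the patch entries
  with the $1/(p^2 C)$ normalization. On a grid of odd side $n$ the
  masked patch is the center tile; because the package's default working
  size of 32 px is not divisible by any odd $n \ge 3$, an explicit
  `patch_size` argument selects a centered box instead (the pretraining
  pipeline uses $p = H/4$, i.e. an 8 px patch at 32 px).
* **Jigsaw puzzle.** The image is cut into an $n \times n$ tile grid,
  shuffled by a permutation $\pi$ drawn from a fixed catalog, and the
  network classifies *which* permutation was applied; the loss is the
  cross-entropy $-\log \hat y_\pi$ with the probability clamped below at
  $10^{-12}$ so degenerate predictions stay finite. The catalog always
  starts with the identity and is built greedily to maximize the minimum
  pairwise Hamming distance (all $4! = 24$ permutations for the default
  $2\times 2$ grid; sampled candidates for larger grids, where
  enumeration is infeasible). Inverse permutations are precomputed and
  the permute-then-invert round trip is bit-exact.

All three tasks share one autoencoder architecture: four conv+ReLU
encoder stages (kernel 4, stride 2, padding 1; channels
$4 \to 64 \to 128 \to 256 \to 512$, each stage halving the spatial side)
mirrored by four transposed-convolution decoder stages ending in a
3-channel sigmoid. At a 32 px input the bottleneck is $2\times 2\times
512$ and the per-stage parameter counts are 4160, 131200, 524544 and
2097664, with 3075 parameters in the final decoder stage — these counts
are asserted exactly in the test suite. The first-stage count forces
**4 input channels**; the package therefore feeds every encoder a
4-channel stack of the RGB planes plus the luminance plane (the
colorization encoder receives the luminance replicated in place of RGB,
so it never sees color). The jigsaw task replaces the decoder with a
flatten + linear head over the permutation catalog during pretraining;
only encoders are carried forward into fusion.

## Fusion scenarios and downstream training

Seven scenarios fuse the pretrained encoders: each single task (`Cl`,
`PPred`, `JigPuzz`), each pair, and the full triple
(`Cl-PPred-JigPuzz`). The forward path applies each encoder to its
task-appropriate input stack, flattens and concatenates the bottleneck
features, and classifies through linear → ReLU → dropout (0.3) → linear
to 3 logits. Head widths are always computed from the actual concatenated
feature length — 2048 per encoder at 32 px, $512\cdot 8\cdot 8$ per
encoder at 128 px — with hidden widths of 1024 for two-encoder fusion and
512 otherwise.

Downstream training choices, where the protocol was genuinely open:

* **Partial fine-tuning.** Whether the pretrained encoders stay frozen
  downstream is not fixed by the training protocol we follow; pure linear
  probing underfits the jigsaw-only scenario. The default
  (`fine_tune = "last_block"`) freezes the first three encoder stages
  (their features are precomputed once) and trains the final convolution
  stage jointly with the head, which keeps per-epoch cost near that of a
  linear probe while letting the representation adapt. `fine_tune =
  "none"` gives the pure frozen probe.
* **Feature standardization.** The fused feature vector is standardized
  per dimension using training-set statistics taken at initialization and
  frozen thereafter (a fixed affine layer stored in the head, applied
  identically at prediction time). Raw conv-feature scales vary by
  orders of magnitude across dimensions and make head optimization
  needlessly ill-conditioned.
* **Validation split and early stopping.** The study names only train and
  test sets; for early stopping a validation set (15% of training frames
  by default) is carved *patient-wise* from the training side. Training
  stops when the validation loss fails to improve by at least `min_delta
  = 1e-4` for `patience = 5` consecutive epochs, and the best epoch's
  weights are restored. Pretext pretraining keeps its fixed 20 epochs
  (Adam, learning rate $10^{-3}$, batch size 32) with no early stopping.
* **Regularization.** SMOTE operates on flattened pixel vectors of
  training frames only: each synthetic minority sample is $x + \lambda
  (x_{nn} - x)$, $\lambda \sim U(0,1)$, with $x_{nn}$ one of the
  $k = 5$ Euclidean nearest same-class neighbors, until every class
  matches the majority count. Augmentation (rotation up to ±15°, flips,
  zoom 0.9–1.1, brightness ±0.1, contrast 0.9–1.1) appends one seeded
  augmented copy per training frame. Both record the manifest indices
  they touched, so leakage into validation or test data is checkable by
  instrumentation, and both are applied strictly inside the training
  side of the patient-wise split.

Two architectural variants mirror the interpretability extensions: a
spatial soft-attention pooling over each encoder's bottleneck (softmax
weights over positions, output the weighted feature sum, so uniform
features yield the mean) and a single transformer encoder block
(4 heads, model width 512, feed-forward width 1024, pre-classifier,
sequence shape preserved). Those module sizes are not fixed by the
protocol; they were chosen small enough to train on a desk machine and
are validated by finite-difference gradient checks. A contrastive-style
baseline is also provided: a backbone (the small CNN encoder, or a
randomly initialized ResNet-50 bottleneck topology — no pretrained
weights are downloaded, and bias convolutions stand in for batch
normalization) with a two-layer projection head to a 128-dimensional
embedding, a linear classifier, label-smoothed cross-entropy
($\varepsilon = 0.1$), Adam at $10^{-4}$ with weight decay $10^{-5}$,
and a plateau learning-rate scheduler.

## Explainability

`grad_cam()` computes, for any convolutional layer, channel weights as
the spatial mean of $\partial z_c / \partial A$ (the target-class logit's
gradient with respect to the layer's activations), forms
$\mathrm{ReLU}(\sum_k w_k A_k)$, upsamples bilinearly to the input size
and min-max normalizes per image to $[0,1]$. The default layer is the
last encoder convolution, whose $2\times2$ map at 32 px aligns exactly
with image quadrants. An identically zero map (zero gradients, or no
positive channel contribution — which legitimately happens for some
input/class pairs) is returned as all zeros with a warning rather than
NaNs; a constant positive map normalizes to all ones. Overlays blend a
perceptually uniform colormap (viridis) with the frame:
$(1-\alpha)\,\mathrm{img} + \alpha\,\mathrm{cmap}(h)$.

## The synthetic data generator

The study's 40-patient dataset is private, so the package ships a
generator that emulates the statistical structure the framework relies
on, without claiming visual realism:

* three classes separated by hue band (deep red for the Z-line class,
  pink-orange for esophageal, yellow-tinged for antrum/pylorus — a warm
  palette, as in endoscopy), by the number of bright mucosal-like blobs
  (1/3/6) and by the spatial frequency of a sinusoidal texture (2/5/9
  cycles), under a radial vignette mimicking endoscope optics;
* per-patient appearance shifts (small hue/saturation/value offsets) and
  per-pixel noise, with frames assigned round-robin so every patient
  holds frames of every class;
* the study's class imbalance (766 / 1589 / 1256 frames, 3611 total)
  reproduced on demand;
* determinism: the manifest is a pure function of the seed.

A pixel-mean nearest-centroid classifier separates the generated classes
with high accuracy — asserted in the tests — which is what makes the
end-to-end learning checks meaningful: if a fusion scenario fails to
reach high held-out accuracy on this fixture, the training machinery is
at fault, not the data. What passing these tests does **not** show is
performance on real endoscopy: real frames have specular highlights,
motion blur, bubbles, far subtler class boundaries, and patient effects
that do not reduce to an affine appearance shift. The generator is a
test harness, not a claim about clinical data. A second fixture
(`generate_quadrant_dataset()`) puts the entire class signal into one
image quadrant over neutral noise, giving ground truth for saliency
localization.

## Numerical choices and problem sizes

The neural engine is written in R: convolutions are im2col gathers
followed by BLAS matrix products, the col2im scatter is a precomputed
sparse-matrix multiply, and transposed convolutions are the exact
adjoints of the corresponding convolutions (weight count
$\mathrm{in}\cdot\mathrm{out}\cdot k^2 + \mathrm{out}$, matching the
published accounting). Adam uses the scalar bias-correction
reformulation. All layers — including the transformer block's multi-head
attention and layer norms — are verified against central finite
differences. Everything is double precision; two runs with the same seed
produce identical histories on CPU.

Default working size is 32 px (the size the published shape chain and
parameter counts imply), with 128 px supported; the resize mismatch
between those two is resolved by making `image_size` a parameter. The
test suite trains on 150-frame fixtures at 32 px (all seven scenarios,
three seeds, the full 20-epoch pretext protocol) and on 16 px frames for
unit-level checks; these sizes were chosen so the whole suite runs on a
single desk CPU in well under half an hour while still exercising the
complete training path. Table rows of the published decoder mirror the
encoder's parameter counts, which is inconsistent with the standard
transposed-convolution formula except for the final 3075-parameter
stage; the standard formula is implemented, and only the encoder column
and that final row are asserted.

## Known limitations

* The engine targets desk-scale experiments; it is single-threaded
  R + BLAS and does not attempt GPU-class throughput or full ResNet-50
  training.
* The jigsaw loss is read as cross-entropy over the permutation catalog
  (its printed summation bound — the number of tiles — is internally
  inconsistent with classification over permutations).
* SMOTE interpolates raw pixels; on real images this produces ghosting
  artifacts, which is faithful to the protocol but worth knowing.
* Patient-wise splitting guarantees no patient-level leakage, but the
  greedy largest-first packing only approximates the requested training
  fraction when patient sizes are lumpy; when the fraction is
  unreachable without emptying the test side, the smallest patient is
  held out and a warning is raised.
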