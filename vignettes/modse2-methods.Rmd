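---
title: "Roto-translation equivariant networks for 2-D medical images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Roto-translation equivariant networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modse2)
```

## The problem and the model

Anatomical structures in 2-D medical images — tumors in axial MRI slices,
lesions, cells — appear at arbitrary orientations and positions.  An ordinary
convolutional network is equivariant to translations only: rotating its input
does not rotate its features, so it must learn each orientation separately,
typically through rotation augmentation.  This package builds networks that
are *equivariant to the discrete roto-translation group* SE(2) by
construction, so a rotation of the input produces a predictable
transformation of every intermediate feature map, and classification outputs
can be made exactly invariant by pooling over orientations.

The group is discretized to `O` orientations, `theta_k = 2*pi*k/O`.  A group
element `g = (k, t)` pairs an orientation index with a translation; elements
compose as `(k, t) . (k', t') = (k + k' mod O, R_theta t' + t)` and act on
images by the pullback `(g.I)(p) = I(g^{-1} p)` (`se2_element()`,
`se2_compose()`, `act_on_image()`).  Three layer families realize the model:

* **Lifting convolution** (`lifting_conv`): correlates a planar image with
  `O` rotated copies of one base filter, producing a feature map on the
  group, shape `[H, W, O, C]`.  Rotating the input by `theta_r` rotates the
  output spatially *and* cyclically shifts the orientation axis by `+r`.
* **Group convolution** (`group_conv`): convolution of group feature maps
  with kernels `[kh, kw, O, Cin, Cout]`, where the kernel transform couples a
  spatial rotation with a cyclic shift of the kernel's orientation axis.  The
  equivariance contract is the same as for lifting.
* **Group deconvolution** (`group_deconv`): the exact linear adjoint of the
  group convolution with the same kernel, stride and padding, used for
  equivariant upsampling in the segmentation decoder.

Orientation pooling (`orientation_project`, the mean over the orientation
axis) converts equivariance into invariance: together with global spatial
averaging it makes the classification head's output invariant to
roto-translations of the input.  Channel recalibration (`se_recalibrate`, a
squeeze-and-excitation bottleneck) and batch normalization
(`equivariant_batch_norm`) are made group-compatible by pooling their
statistics over the orientation axis as well as space — a per-channel
statistic is invariant under the group action, so gating or normalizing with
it commutes with the action.  The converse designs (statistics or learned
parameters indexed by absolute orientation) break equivariance; the
verification harness ships both broken variants to demonstrate that its
checks detect exactly this class of error.

## Kernel rotation and numerical exactness

Rotating a small odd-sized kernel is a fixed linear map of its spatial taps.
The package materializes that map as a `(kh*kw) x (kh*kw)` operator built by
bilinear interpolation with zero fill — an exact permutation matrix when the
angle is a multiple of 90 degrees.  Two consequences drive the whole test
strategy:

* for `O` divisible by 4, quarter-turn rotations of images, feature maps and
  kernels are exact permutations, so every equivariance identity can be
  asserted to floating-point accumulation (`~1e-14`) rather than to an
  interpolation tolerance;
* the backward pass through kernel rotation is the transpose of the same
  operator, which keeps hand-written gradients exact (finite-difference
  checks agree to `~1e-9`).

At angles off the quarter-turn grid, bilinear interpolation limits accuracy:
rotating a unit-sigma 5x5 Gaussian by 45 degrees deviates from itself by
about 0.09 in max-abs.  Checks involving such angles therefore use
interpolation-scale tolerances (0.02-0.1), and the exactness claims are
always made on the quarter-turn subgroup.

A subtlety worth recording: on even-sized grids the *stride-2* transposed
convolution cannot be exactly equivariant to quarter turns, because its
sampling lattice (every second pixel from the top-left) is not symmetric
about the image center.  The decoder therefore upsamples by the exact
adjoint of the encoder's average pooling (uniform 2x2 block spreading) and
follows it with a stride-1 transposed group convolution; the composite is
the exact adjoint of an encoder stage, and the segmenter is exactly
equivariant end to end.  The standalone `group_deconv()` operation keeps the
strided-adjoint semantics, and its adjointness is verified directly.

Zero padding has one more consequence: affine normalization maps background
zeros away from zero, so commutation checks that translate content compare
only rotation actions (bijections of the grid) for normalization layers, and
keep inputs supported away from the border for convolution layers.

## Reference architectures

`build_classifier()` follows the pipeline: 3x3 stem convolution (32 filters
by default), lifting layer (64 filters), average pooling, then
group-convolution blocks (group conv, batch norm, squeeze-excitation, ReLU,
average pooling; default widths 64 and 128), orientation projection, global
average pooling, and a fully connected head (hidden width 256, dropout 0.4,
softmax).  Average pooling is used throughout rather than max pooling, which
suppresses the fine-scale activations this model family is designed to
retain.  One deliberate design choice: an *unconstrained* stem kernel before
the lifting layer would break rotation equivariance at the first layer (a
plain 3x3 convolution does not commute with rotations), so the stem's taps
are tied over the C4 rotation orbits of the 3x3 grid (center, edge orbit,
corner orbit; 3 free parameters per channel pair).  This preserves the stem's
role as a learned planar pre-filter while commuting exactly with quarter
turns.

`build_segmenter()` reuses the classifier trunk as a U-Net-style encoder and
mirrors it with group-deconvolution stages; encoder feature maps are
concatenated at matching resolutions (the lifting output provides the
full-resolution skip) and merged by 1x1 group convolutions, followed by
orientation projection, a 1x1 convolution and a sigmoid.  Whether skip
connections exist at all, and how they merge, was an open design point;
concatenation was chosen because it is the conventional U-Net reading.

`build_baseline_cnn()` constructs a plain CNN with the same depth pattern and
spatial schedule, its widths rescaled so the trainable parameter count lands
within 10% of the matched equivariant model — the control for the
rotation-robustness experiment.  Parameter accounting
(`count_layer_parameters`) implements both the as-printed grouped-convolution
formula, which divides the output channels by the group count, and the
conventional grouped count; the two disagree for `G > 1` and both are
exposed because the as-printed variant cannot be reconciled with standard
grouped convolutions.  SE(2) group kernels are counted as
`kh*kw*O*Cin*Cout` (+ bias): channel-grouping formulas do not describe
orientation-indexed kernels.

## Training

There is no automatic-differentiation framework in this package's
dependency set; every layer carries a hand-written reverse-mode gradient,
validated against central finite differences at machine precision.  The
optimizer is Adam (learning rate 0.001) with weight decay 0.0005 applied to
convolution and fully connected weights (not biases or normalization
parameters), categorical cross-entropy for classification and the smoothed
Jaccard (soft IoU) loss, `1 - (sum(p t) + 1) / (sum(p) + sum(t) - sum(p t) + 1)`,
for segmentation.  Default batch sizes are 8 (classification) and 32
(segmentation); reference epoch budgets are 100 and 70, while the desk-scale
experiments below use far fewer.  Runs are deterministic given the seed
(shuffling, dropout and initialization all flow from it).  After the last
epoch the batch-norm running statistics are recalibrated: one forward pass
over the training set with the final weights (dropout disabled) replaces
the exponential moving averages with exact population statistics.  Short
training schedules leave the moving averages lagging behind the rapidly
moving weights, which otherwise depresses eval-mode accuracy well below
train-mode accuracy; recalibration closes that gap and is switchable via
`train_config(refresh_stats = )`.  No k-fold
cross-validation is performed; each experiment uses a single fixed split
with a recorded seed, and no early stopping is used except where a protocol
explicitly bounds the epoch count ("up to 25 epochs"), where training stops
once the epoch loss has not improved by 0.001 for 3 consecutive epochs.

## Synthetic data: what it emulates and what it does not

All experiments run on seeded generators (`gen_classification_set`,
`gen_segmentation_set`, `gen_finescale_set`).  Images are built as
`background (0.2) + offset (0.5) * support + N(0, 0.1)`, clipped to [0, 1],
so the ground-truth mask is exactly the set of pixels that received the
foreground offset.  The classification task draws one of five shapes (disk,
square, triangle, annulus, cross — chosen so that discrimination is
orientation-sensitive), rotated uniformly over the full circle unless
"upright" mode is requested, translated within a jitter range; classes are
balanced.  The segmentation task renders 1-3 smooth blobs (unions of
randomly oriented, boundary-perturbed ellipses).  The fine-scale task stamps
exactly one axis-aligned bright square with side drawn from {3, 5, 7, 9}
pixels at a whole-pixel position, so mask areas are exactly `s^2`.

These generators emulate orientation variability, fine-scale features and a
controlled contrast-to-noise ratio (offset 0.5 over sigma 0.1).  They do not
emulate MRI physics — no bias fields, Rician noise, partial-volume effects,
anatomy-correlated backgrounds or annotation noise.  Passing the experiments
below therefore demonstrates the *geometric* claims (equivariance helps
under orientation shift; small features survive the architecture) rather
than clinical-grade performance.

## The two experiments

**Rotation robustness** (`run_rotation_robustness`): 2000 upright-only
images are split 1200 / 400 / 400 into train, upright test and rotated test
(the rotated split is generated with full-circle poses).  Both the
equivariant classifier and the parameter-matched plain CNN are trained for
15 epochs with no rotation augmentation, and the reported quantity is each
model's accuracy drop from the upright to the rotated split.  The expected
outcome is directional: the equivariant model's drop is smaller.  Inputs are
resized to 32x32 for this experiment (the pipeline's uniform-resolution
preprocessing step), which keeps both models' training in the minutes range
on one CPU core.

**Fine-scale detection** (`run_finescale_experiment`): 400 training and 100
test images at 64x64, segmenter preset `O = 8`, encoder widths [16, 32],
Jaccard loss, up to 25 epochs.  A feature counts as *detected* when its
per-image Dice reaches 0.5, and a size counts as *reliably* detected when at
least 90% of test images at that size are detected; both thresholds are
configuration fields, not constants.  The report lists the detected fraction
per side length and the smallest reliable side.  The headline expectation is
that squares of 5 pixels and below are reliably segmented.

Desk-scale presets (`desk_cls_config()`, `desk_seg_config()`) fix the model
sizes used by both experiments: classifier at 32x32 with widths 4/8/[8, 16],
segmenter at 64x64 with widths 4/4/[16, 32], a pooling factor of 4 after the
lifting layer, and 1x1 decoder kernels.  In the segmenter preset the
full-resolution lifting skip carries the spatial detail, so the encoder
blocks can work on a 16x16 grid and the decoder can mix channels with 1x1
kernels; a 3x3 transposed group convolution at full resolution would
dominate the compute budget many times over for no measurable gain on this
task.  These problem sizes are the package's choices for single-core
reproducibility; every width, extent, pooling factor and epoch count is a
configuration field.

## Preprocessing and IO

`preprocess()` resizes to a uniform extent (bilinear), applies global
256-bin histogram equalization (CDF mapping; constant images pass through
unchanged) and rescales to [0, 1].  `augment()` draws one rotation within
±15 degrees and one scale within ±10% and applies them jointly to image
(bilinear) and mask (nearest, re-binarized).  Augmentation defaults off for
the equivariant models — reduced reliance on augmentation is the point of
the architecture — and the baseline comparison deliberately trains *both*
models without it, isolating the architectural effect.  PNG (8-bit write,
8/16-bit read) and NIfTI-1 are supported; NIfTI slices are taken along the
last stored axis as-is, with no radiological re-orientation.

## Known limitations

* Equivariance is exact only on the quarter-turn subgroup; intermediate
  angles are interpolation-limited (bounds above).
* The stem constraint (C4-tied taps) slightly reduces the stem's expressive
  power relative to an unconstrained convolution of equal width.
* Strided transposed convolutions are provided as operations but not used
  for upsampling inside the reference segmenter, for the lattice-symmetry
  reason above.
* Training is CPU-bound R; the reference-scale configurations (256x256,
  widths 32/64/[64, 128], 100/70 epochs) are expressible but intended for
  workstations, not for the desk-scale test cycle.
* Zero-denominator metrics are reported as `NA` (serialized `null`), and the
  both-empty-mask convention `Dice = IoU = 1` is recorded in every report.
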