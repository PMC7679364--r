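---
title: "neoseg: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neoseg: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical choices behind the
package: the network and its variants, the complexity-accounting
convention, the augmentation and histogram-matching definitions, the fold
optimizer, and what the synthetic fixtures do and do not establish about
real clinical data.

## The segmentation problem

Camera-based vital-sign monitoring of preterm infants (photoplethysmography
imaging) needs a skin region of interest tracked automatically through
video, at the recording rate, including under invisible near-infrared
illumination. The package segments each frame into background plus six
body parts — head, torso, left/right arm, left/right leg — with the
convention that only naked skin carries a part label: clothing, electrodes
and other occlusions are background, since covered skin is useless for
photoplethysmography.

## Network

The encoder is a modified ResNet-50: the global-average-pool and
fully connected classification head are removed and the feature maps at
strides 2, 4, 8, 16 and 32 are exposed. This is the unique reading of
"modified ResNet-50" consistent with the encoder's parameter total of
23,508,032 (3-channel input; affine batch-norm parameters counted), which
`countParameters(modelSpec("batchnorm"), section = "encoder")` reproduces
exactly.

The decoder is FCN-style. The deepest (stride-32) map passes through a
1 × 1 "score" convolution to a small working width (default 16 channels);
each stage then upsamples ×2 with a stride-2, kernel-4 transposed
convolution, concatenates a 1 × 1-scored encoder skip, and fuses with a
3 × 3 convolution; a final ×2 upsampling restores input resolution before
the 1 × 1 classifier and per-pixel softmax. Four variants:

* **batchnorm** — every decoder convolution (including transposed ones) is
  followed by batch normalization, then ReLU.
* **dropout** — decoder normalization is replaced by dropout (default rate
  0.5) after the activations; the encoder keeps its normalization layers so
  pretrained encoder weights remain usable. (The alternative reading — that
  the *encoder's* normalization is replaced — would discard those weights;
  we implement the decoder reading.)
* **bilinear** — transposed convolutions are replaced by fixed bilinear
  ×2 interpolation; the upsampling path carries zero trainable parameters.
* **unconnected** — no skip concatenations; the decoder sees only the
  deepest encoder output.

The exact layer inventory of the original decoder is not recoverable from
its published description; this reference decoder targets the same order
of parameter budget (the published figure is 69,860; width 16 gives
~102k) and is not claimed layer-identical.

Input images in [0, 1] are normalized to (x − 0.5)/0.25 before the stem.
Spatial dimensions must be divisible by 32 so that five stride-2 stages
divide evenly and the decoder restores the exact input size. Coordinates
are 1-based (row, column) as usual in R; class indices are 0-based
(0 = background) to match the published schema. A single-channel (NIR)
image fed to a 3-channel network is replicated across channels by default,
so pretrained RGB encoder weights load unchanged; alternatively
`inputChannels = 1` builds a mono stem (pretrained stem kernels are then
averaged over the channel axis).

### Initialization

Weight initialization is deterministic under the model seed. Transposed
convolutions start as bilinear-interpolation kernels on the identity
channel mapping (standard FCN practice — the decoder begins as a
meaningful upsampler rather than noise); batch normalization starts at
unit gain except the residual-final layers of each bottleneck, whose
scales start at zero so every block begins as the identity (the standard
zero-init-residual option).

Convolution weights are Gaussian with variance gain²/fan-in, and the gain
is deliberately low where normalization follows: gain² = 1/8 in the
encoder and 1/50 in the decoder (the classifier, and decoder convolutions
of the dropout variant, which lack a following normalization, use the
ReLU gain² = 2). The reasoning: batch normalization makes the forward
pass invariant to each convolution's weight scale, but Adam caps every
parameter's movement near the learning rate per step, so the *relative*
adaptation rate of a normalized layer scales inversely with its weight
norm. With the protocol's fixed rate of 1e-4, low-gain starts let the
network fit small datasets in hundreds rather than thousands of steps;
the forward contracts and complexity figures are unaffected. The gains
were selected on a small synthetic proxy task (4 scenes at 64 px) and
then frozen.

## Complexity accounting

`countFMAs()` uses one stated convention everywhere, printed in every
report header: a convolution costs k²·C_in·C_out·H_out·W_out multiply-adds
(bias folded into the accumulate); a transposed convolution is counted
symmetrically over its input positions; fully connected layers cost
fan-in × fan-out; batch normalization, ReLU, pooling, fixed bilinear
interpolation and elementwise residual additions cost one FMA per output
element; concatenation, dropout and the final softmax are free. One GFMA
is 10⁹ FMAs, reported rounded half-up to two decimals.

Under this convention the encoder at 320 × 320 × 3 (the pre-training
resolution, which we adopt as the audit operating point) counts
8,341,094,400 convolution MACs plus 53,964,800 elementwise FMAs =
8.3951 GFMAs → printed 8.40. Elementwise-op conventions are worth a
fraction of a percent: excluding residual additions gives 8.38, excluding
all elementwise ops 8.34. The same counter applied to an unmodified
VGG-16 classifier at 320 × 320 (13 convolutions, five pools, fully
connected layers sized for the 10 × 10 × 512 pool-5 map) gives
31.32 GFMAs of convolution MACs + 0.23 fully connected + 0.03 elementwise
= 31.58 GFMAs; published audits of the same network quote 31.51, a 0.2%
difference attributable entirely to which elementwise terms and fully
connected sizing a counter includes. We report our convention's value and
do not tune the convention per network.

## Augmentation

All random draws are uniform. Defaults: scale factor on [0.7, 1.4]
(upscaled content randomly cropped, downscaled content randomly placed on
a black background with background label); rotation on [−30°, 30°] about
the canvas center, exposed corners black/background; horizontal flip with
probability 0.5 — left/right part labels are *not* exchanged by default,
matching the clinical training runs (the swap is available via
`swapLeftRightLabels`); brightness/contrast/saturation factors on
[0.9, 1.1]. The operation order is fixed (scale → rotate → flip → color:
geometric before photometric) for reproducibility. Images are resampled
bilinearly and masks nearest-neighbor with identical geometry, so no new
class indices can appear. The photometric operators are defined as:
brightness — multiplicative gain; contrast — scaling of the deviation from
the scalar image mean; saturation — interpolation toward the per-pixel
channel mean. Only the [0.9, 1.1] range is fixed by the protocol; the
operator forms are package definitions. The pre-training profile enables
only scaling/cropping and rotation.

## Virtual NIR by constrained histogram matching

Only the red channel of an RGB frame is used (spectrally closest to 940-nm
NIR). A monotone 8-bit map T is fitted per source intensity k: among
target intensities j whose cumulative histogram ĉ_t(j) does not exceed the
source cumulative ĉ_s(k) by more than half the (normalized) source
histogram count at k, T(k) is the j minimizing |ĉ_t(j) − ĉ_s(k)|, ties to
the smallest intensity; if no intensity satisfies the bound the smallest
overshoot is taken. This mirrors the classic constrained histogram
-matching rule; monotonicity follows by construction and is asserted in the
validity method. Two consequences worth knowing: (i) when source and
target histograms are equal, T is the identity on *occupied* bins — empty
bins may map downward under the smallest-intensity tie-break, which never
affects any pixel; (ii) with 8-bit data the map composes exactly with
quantization, so matching an image to its own histogram returns the image.
In the intended workflow the reference histogram comes from one real NIR
frame of the same recording, so no information crosses recordings (or
folds).

## Keyframes, folds

Keyframe ranking scores each consecutive-frame transition by the mean
absolute intensity difference over all pixels and channels — larger
differences indicate movement — and returns the highest-scoring frame
indices subject to a minimum index gap, ties to the earlier frame. The
original annotation workflow used such rankings only as *guidance* for
manual selection, so this operation is an assistive ranker, not a
reconstruction of a published selection rule.

Fold assignment is grouped by recording: recordings are sorted by frame
count (descending, ties by id) and greedily placed into the fold that
minimizes the sum over (modality, origin, orientation) cells of squared
deviations of per-fold frame counts. Greedy minimization is deterministic
and auditable (`foldBalanceCost()`); on small instances it attains the
enumerated optimum (see the test suite). The published folds were
"optimized" without a stated algorithm; greedy square-deviation
minimization is this package's choice.

## Training harness

Per-pixel cross-entropy (uniform pixel weights), Adam with β₁ = 0.9,
β₂ = 0.999, ε = 1e-8, initial rate 1e-4; constant rate in the pre-training
profile, halved every 30 completed epochs in the clinical profile. One
epoch is one pass over the training split. Dataset-level metrics: confusion
counts are pooled over all evaluation images before ratios, the
FCN-literature convention; ACC is class-wise recall TP/(TP+FN), the only
per-class reading of "accuracy" that yields one value per class. Batch
size and epoch budgets are configuration with documented defaults (8 and
150 in the overfit configuration below) since no published values exist.

All kernels run in the package's C++ backend; convolution GEMMs accumulate
in single precision (standard deep-learning practice; parameters,
optimizer state and all other ops are double). Evaluation-mode forwards
are bitwise deterministic for fixed weights and input.

### What the synthetic fixtures show — and what they don't

The scene generator draws geometric-primitive "neonates" (large elliptical
head — neonatal proportions — rectangular torso, four limb bars; an adult
preset shrinks the head for contrast) over cluttered backgrounds with
per-part brightness tints, optional clothing occlusion (occluded pixels
are background-labeled), illumination gradients, sensor noise, and
NIR-style underexposure (single channel, reduced gain). Fixed constants in
code; everything is seeded and reproducible. Training-scale choices in the
test suite (scenes of 64–96 px, ≤ 8 images, ≤ 150 optimizer steps) are
sized so a laptop CPU reproduces them in minutes.

Passing the overfit and cross-validation checks on these fixtures
establishes that the network, loss, optimizer and data plumbing are wired
correctly — gradients flow to every layer, memorization is possible,
grouped evaluation is honest. It does **not** establish clinical
segmentation accuracy: real neonatal frames have soft part boundaries,
skin-tone/background confusions, motion blur and genuinely inhomogeneous
NIR illumination that geometric primitives do not emulate. Reported
clinical-scale scores require the original recordings and GPU-scale
training and are out of scope here.

## Known limitations

* CPU-only; practical for the desk-scale experiments above, not for
  960 × 576 video training.
* The reference decoder approximates the published budget, not its exact
  layer list (not recoverable from the text).
* The VGG-16 audit differs from the published 31.51 GFMAs by 0.2%
  (convention sensitivity, discussed above).
* The histogram-matching overshoot rule follows the classic constrained
  formulation; the published description is ambiguous about the exact
  tolerance term.
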