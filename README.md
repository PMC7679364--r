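# neoseg

Body-part segmentation of neonatal video for camera-based vital-sign
monitoring (photoplethysmography imaging, PPGI). Continuous monitoring in
the NICU needs a region of interest — ideally naked skin of a specific body
part — detected automatically in every frame, in real time, and also under
invisible near-infrared (NIR) illumination where color-based skin detection
is impossible. `neoseg` implements a fully convolutional encoder-decoder
network for this task together with everything needed to study it without
clinical recordings: complexity accounting, augmentation (including
virtual-NIR synthesis), grouped cross-validation, metrics, and a synthetic
scene generator.

The package is aimed at researchers in camera-based patient monitoring and
medical image analysis who want a transparent, dependency-light R
implementation of the full pipeline.

## The model

Frames are segmented into seven classes — background plus head, torso,
left/right arm, left/right leg; only naked skin carries part labels,
occluded regions are background. The network is an encoder-decoder FCN:

* **Encoder** — a modified ResNet-50: the ImageNet classification head is
  removed and feature maps are exposed at strides 2, 4, 8, 16 and 32. It
  has exactly 23,508,032 trainable parameters (3-channel input) and costs
  8.40 GFMAs per forward pass at 320 × 320 (one FMA = one fused
  multiply-add; elementwise ops counted at one FMA per output element).
* **Decoder** — an FCN-style upsampling path: a 1 × 1 score convolution on
  the deepest map, then per stage a stride-2 transposed convolution
  (kernel 4, bilinear-initialized), concatenation with a 1 × 1-scored
  encoder skip, and a 3 × 3 fusion convolution; a final ×2 upsampling
  restores input resolution before the per-pixel softmax. Four variants:
  `batchnorm` (BN after every decoder convolution), `dropout` (dropout
  replaces decoder BN), `bilinear` (fixed bilinear upsampling, zero
  trainable upsampling parameters) and `unconnected` (no skips).
* **Training** — per-pixel cross-entropy, Adam (lr 1e-4, β₁ = 0.9,
  β₂ = 0.999, ε = 1e-8); constant rate for pre-training, halving every 30
  epochs for clinical fine-tuning.
* **Metrics** — per class c: IoU = TP/(TP+FP+FN) and class-wise pixel
  accuracy ACC = TP/(TP+FN), accumulated over the image set before the
  ratio; means are over the six foreground classes.
* **Virtual NIR** — the red channel of an RGB frame is pushed through a
  monotone 8-bit intensity map T fitted so the cumulative histogram of the
  output tracks that of a real NIR reference frame, subject to an
  overshoot bound of half the source histogram mass per level.
* **Folds** — recordings (never frames) are assigned to k = 5 folds by a
  greedy balance optimizer over per-modality frame, origin and orientation
  counts, so whole subjects are held out.

All tensor kernels (convolution, transposed convolution, batch
normalization, pooling, bilinear warping) are implemented in the package's
C++ backend on BLAS GEMMs; no external deep-learning runtime is required.

## Worked example

```r
library(neoseg)

## complexity audit of the batchnorm variant at the pre-training resolution
rep <- complexityReport(modelSpec("batchnorm"), 320, 320)
totalsTable(rep)[, c("section", "params", "gfmas")]
#>   section   params gfmas
#>   encoder 23508032  8.40
#>   decoder   102048  0.38
#>      head      119  0.01
#>     total 23610199  8.78

## synthesize a labeled scene, train briefly, evaluate
scene <- generateScene(sceneSpec(canvas = c(64, 64), seed = 1))
ds <- list(list(image = scene$image, mask = scene$mask))
fit <- trainModel(ds, trainConfig(epochs = 5, batchSize = 1,
                                  inputSize = c(64, 64), seed = 1))
round(fit$log$loss, 3)
#> [1] 1.867 1.694 1.529 1.389 1.302

## virtual NIR from the red channel
nir_ref <- generateScene(sceneSpec(canvas = c(64, 64), modality = "NIR",
                                   exposureScale = 0.5, seed = 2))
v <- toVirtualNIR(scene$image, imageHistogram(nir_ref$image))
c(red = mean(scene$image[, , 1]), virtual_nir = mean(v))
#>        red virtual_nir
#>  0.3937607   0.1619485
```

The loss falls steadily from its near-uniform start (ln 7 ≈ 1.946) as the
network begins to fit the scene;
the virtual-NIR image is darker than the raw red channel because the
reference frame is underexposed, as real 940-nm recordings are.

A command-line interface wraps the same functions
(`system.file("scripts", "neoseg", package = "neoseg")`), with subcommands
`complexity`, `synth`, `make-folds`, `virtual-nir`, `train`, `predict`,
`evaluate` and `cross-validate`.

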