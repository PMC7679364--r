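Package: neoseg
Title: Encoder-Decoder Body-Part Segmentation for Neonatal RGB/NIR Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Real-time-capable encoder-decoder fully convolutional network for
    six-part body segmentation (head, torso, left/right arm, left/right leg)
    of neonatal RGB and near-infrared video, built on a modified ResNet-50
    encoder with four decoder variants. Includes analytic parameter and
    multiply-add (FMA) complexity accounting, the joint image/mask
    augmentation suite (scale, rotation, flip, color jitter), virtual-NIR
    synthesis by constrained histogram matching of the red channel,
    recording-grouped balanced cross-validation folds, keyframe selection by
    frame differencing, per-class IoU/accuracy metrics, a CPU training
    harness with Adam, and a deterministic synthetic-scene generator so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
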