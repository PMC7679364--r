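#' @import methods
NULL

DECODER_VARIANTS <- c("bilinear", "unconnected", "dropout", "batchnorm")

#' The seven-class body-part schema
#'
#' Class indices are 0-based: 0 background, 1 head, 2 torso, 3 right arm,
#' 4 left arm, 5 right leg, 6 left leg. Display colors follow the annotation
#' palette used for the clinical ground truth (head blue, torso green, right
#' arm red, left arm magenta, right leg cyan, left leg yellow, background
#' black).
#'
#' @return A data.frame with columns `index`, `name`, `color` (hex RGB).
#' @export
#' @examples classSchema()
classSchema <- function() {
  data.frame(
    index = 0:6,
    name = c("background", "head", "torso", "right arm", "left arm",
             "right leg", "left leg"),
    color = c("#000000", "#0000FF", "#00FF00", "#FF0000", "#FF00FF",
              "#00FFFF", "#FFFF00"),
    stringsAsFactors = FALSE
  )
}

#' Declarative description of a segmentation network
#'
#' @slot decoderVariant one of "bilinear", "unconnected", "dropout",
#'   "batchnorm".
#' @slot numClasses number of output classes (>= 2); default 7 =
#'   background + six body parts.
#' @slot inputChannels 1 (monochrome/NIR) or 3 (RGB).
#' @slot usePretrainedEncoder whether encoder weights are loaded from a
#'   local checkpoint instead of random initialization.
#' @slot dropoutRate decoder dropout rate, used by the "dropout" variant
#'   only.
#' @slot decoderWidth channel width of the decoder score/fusion convolutions.
#' @slot randomSeed seed for deterministic weight initialization.
#' @export
setClass("ModelSpec", representation(
  decoderVariant = "character",
  numClasses = "integer",
  inputChannels = "integer",
  usePretrainedEncoder = "logical",
  dropoutRate = "numeric",
  decoderWidth = "integer",
  randomSeed = "integer"
))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(object@decoderVariant) != 1L ||
      !object@decoderVariant %in% DECODER_VARIANTS)
    msg <- c(msg, sprintf("decoderVariant must be one of: %s",
                          paste(DECODER_VARIANTS, collapse = ", ")))
  if (object@numClasses < 2L)
    msg <- c(msg, "numClasses must be >= 2")
  if (!object@inputChannels %in% c(1L, 3L))
    msg <- c(msg, "inputChannels must be 1 or 3")
  if (object@dropoutRate <= 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in (0, 1)")
  if (object@decoderWidth < 1L)
    msg <- c(msg, "decoderWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param decoderVariant decoder variant name.
#' @param numClasses number of classes (default 7).
#' @param inputChannels 1 or 3 (default 3).
#' @param usePretrainedEncoder load encoder weights from a local file.
#' @param dropoutRate decoder dropout rate for the "dropout" variant.
#' @param decoderWidth decoder channel width (default 16).
#' @param randomSeed initialization seed.
#' @return A [ModelSpec-class] object.
#' @export
#' @examples
#' modelSpec("batchnorm")
modelSpec <- function(decoderVariant = c("batchnorm", "bilinear",
                                         "unconnected", "dropout"),
                      numClasses = 7L, inputChannels = 3L,
                      usePretrainedEncoder = FALSE, dropoutRate = 0.5,
                      decoderWidth = 16L, randomSeed = 1L) {
  decoderVariant <- decoderVariant[1L]
  if (!decoderVariant %in% DECODER_VARIANTS)
    stop("unknown decoder variant: '", decoderVariant, "' (expected one of ",
         paste(DECODER_VARIANTS, collapse = ", "), ")")
  new("ModelSpec",
      decoderVariant = decoderVariant,
      numClasses = as.integer(numClasses),
      inputChannels = as.integer(inputChannels),
      usePretrainedEncoder = isTRUE(usePretrainedEncoder),
      dropoutRate = as.numeric(dropoutRate),
      decoderWidth = as.integer(decoderWidth),
      randomSeed = as.integer(randomSeed))
}

#' Realized encoder-decoder segmentation network
#'
#' Holds the layer graph (an ordered list of nodes), the trainable
#' parameters, and batch-normalization running statistics. Built with
#' [buildModel()]; run with [netForward()].
#'
#' @slot spec the [ModelSpec-class] the network was built from.
#' @slot nodes ordered list of layer-graph nodes.
#' @slot params named list of trainable arrays per layer.
#' @slot buffers named list of non-trainable buffers (BN running stats).
#' @export
setClass("SegmentationNetwork", representation(
  spec = "ModelSpec",
  nodes = "list",
  params = "list",
  buffers = "list"
))

#' Per-pixel class probabilities
#'
#' @slot probs array with dim (height, width, numClasses); per-pixel
#'   probabilities summing to 1 over the class axis.
#' @export
setClass("ProbabilityMap", representation(probs = "array"))

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@probs)
  if (length(d) != 3L) return("probs must have dim (height, width, classes)")
  s <- rowSums(matrix(object@probs, prod(d[1:2]), d[3]))
  if (any(abs(s - 1) > 1e-5))
    return("per-pixel class probabilities must sum to 1 (within 1e-5)")
  if (any(object@probs < -1e-12) || any(object@probs > 1 + 1e-12))
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' Per-pixel label mask over the seven-class schema
#'
#' @slot labels integer matrix (height x width) with values in 0..6.
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  if (!is.integer(object@labels)) return("labels must be an integer matrix")
  if (any(!object@labels %in% 0:6))
    return("labels must lie in the 7-class alphabet {0..6}")
  TRUE
})

#' Construct a LabelMask
#' @param labels matrix of class indices in 0..6.
#' @return A [LabelMask-class].
#' @export
labelMask <- function(labels) {
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  new("LabelMask", labels = m)
}

#' @describeIn labelMask extract the integer label matrix.
#' @param x a LabelMask.
#' @export
maskLabels <- function(x) {
  stopifnot(is(x, "LabelMask"))
  x@labels
}

#' Per-layer parameter and FMA accounting
#'
#' @slot perLayer data.frame with one row per layer: name, kind, section,
#'   outH, outW, outC, params, fmas.
#' @slot totals data.frame with parameter/FMA rollups for encoder, decoder,
#'   head and the whole network.
#' @slot inputSize integer (height, width, channels).
#' @export
setClass("ComplexityReport", representation(
  perLayer = "data.frame",
  totals = "data.frame",
  inputSize = "integer"
))

setValidity("ComplexityReport", function(object) {
  pl <- object@perLayer
  if (any(pl$params < 0) || any(pl$fmas < 0))
    return("all counts must be nonnegative")
  tot <- object@totals
  all_row <- tot[tot$section == "total", ]
  if (nrow(all_row) == 1 &&
      (abs(all_row$params - sum(pl$params)) > 0.5 ||
       abs(all_row$fmas - sum(pl$fmas)) > 0.5))
    return("totals must equal the sum of per-layer entries")
  TRUE
})

#' Monotone intensity mapping between 8-bit histograms
#'
#' @slot sourceHist,targetHist 256-bin counts.
#' @slot sourceCdf,targetCdf normalized cumulative histograms.
#' @slot map integer vector of length 256; `map[k + 1]` is T(k) in 0..255.
#' @export
setClass("HistogramMapping", representation(
  sourceHist = "numeric",
  targetHist = "numeric",
  sourceCdf = "numeric",
  targetCdf = "numeric",
  map = "integer"
))

setValidity("HistogramMapping", function(object) {
  if (length(object@map) != 256L) return("map must cover all 256 intensities")
  if (any(diff(object@map) < 0L)) return("T must be monotone nondecreasing")
  if (any(object@map < 0L) || any(object@map > 255L))
    return("T must map into 0..255")
  TRUE
})

#' Joint image/mask augmentation configuration
#'
#' Defaults follow the training protocol: scale factor uniform on
#' [0.7, 1.4], rotation uniform on [-30, 30] degrees, horizontal flip with
#' probability 0.5, and brightness/contrast/saturation factors uniform on
#' [0.9, 1.1]. Left/right part labels are NOT exchanged on flips by default.
#'
#' @slot scaleRange,colorRange numeric length-2 intervals.
#' @slot maxRotationDeg nonnegative rotation bound in degrees.
#' @slot flipProbability probability of a horizontal mirror.
#' @slot swapLeftRightLabels exchange left/right arm and leg labels on flip.
#' @slot enabledOps subset of c("scale", "rotate", "flip", "color").
#' @slot randomSeed seed consumed by [augmentSample()].
#' @export
setClass("AugmentationConfig", representation(
  scaleRange = "numeric",
  maxRotationDeg = "numeric",
  flipProbability = "numeric",
  colorRange = "numeric",
  swapLeftRightLabels = "logical",
  enabledOps = "character",
  randomSeed = "integer"
))

setValidity("AugmentationConfig", function(object) {
  msg <- character()
  if (length(object@scaleRange) != 2L || diff(object@scaleRange) < 0 ||
      object@scaleRange[1] <= 0)
    msg <- c(msg, "scaleRange must be a positive nondecreasing interval")
  if (object@maxRotationDeg < 0) msg <- c(msg, "maxRotationDeg must be >= 0")
  if (object@flipProbability < 0 || object@flipProbability > 1)
    msg <- c(msg, "flipProbability must lie in [0, 1]")
  if (length(object@colorRange) != 2L || diff(object@colorRange) < 0)
    msg <- c(msg, "colorRange must be a nondecreasing interval")
  if (!all(object@enabledOps %in% c("scale", "rotate", "flip", "color")))
    msg <- c(msg, "enabledOps must be a subset of scale/rotate/flip/color")
  if (length(msg)) msg else TRUE
})

#' Construct an AugmentationConfig
#' @param scaleRange uniform scale-factor interval (default c(0.7, 1.4)).
#' @param maxRotationDeg rotation bound (default 30).
#' @param flipProbability horizontal flip probability (default 0.5).
#' @param colorRange brightness/contrast/saturation interval (default
#'   c(0.9, 1.1)).
#' @param swapLeftRightLabels exchange left/right labels when mirroring
#'   (default FALSE, matching the clinical training runs).
#' @param enabledOps which operations run (default all four).
#' @param randomSeed draw seed.
#' @return An [AugmentationConfig-class].
#' @export
augmentationConfig <- function(scaleRange = c(0.7, 1.4), maxRotationDeg = 30,
                               flipProbability = 0.5, colorRange = c(0.9, 1.1),
                               swapLeftRightLabels = FALSE,
                               enabledOps = c("scale", "rotate", "flip", "color"),
                               randomSeed = 1L) {
  new("AugmentationConfig", scaleRange = as.numeric(scaleRange),
      maxRotationDeg = as.numeric(maxRotationDeg),
      flipProbability = as.numeric(flipProbability),
      colorRange = as.numeric(colorRange),
      swapLeftRightLabels = isTRUE(swapLeftRightLabels),
      enabledOps = enabledOps, randomSeed = as.integer(randomSeed))
}

#' Recording-grouped fold assignment
#'
#' @slot foldOf named integer vector: recording id -> fold in 1..k.
#' @slot k number of folds.
#' @slot balanceReport data.frame of per-fold frame totals by modality,
#'   origin and orientation.
#' @export
setClass("FoldAssignment", representation(
  foldOf = "integer",
  k = "integer",
  balanceReport = "data.frame"
))

setValidity("FoldAssignment", function(object) {
  ids <- names(object@foldOf)
  if (is.null(ids) || anyDuplicated(ids))
    return("every recording must be assigned exactly once")
  if (any(object@foldOf < 1L) || any(object@foldOf > object@k))
    return("fold indices must lie in 1..k")
  TRUE
})

#' Adam learning-rate schedule
#'
#' `decayMode = "constant"` keeps the rate fixed (the pre-training
#' protocol); `"step_half_every_30"` halves it every 30 completed epochs
#' (the clinical fine-tuning protocol).
#'
#' @slot initialLr initial learning rate (default 1e-4).
#' @slot beta1,beta2,epsilon Adam moment constants.
#' @slot decayMode "constant" or "step_half_every_30".
#' @export
setClass("OptimizerSchedule", representation(
  initialLr = "numeric",
  beta1 = "numeric",
  beta2 = "numeric",
  epsilon = "numeric",
  decayMode = "character"
))

setValidity("OptimizerSchedule", function(object) {
  if (!object@decayMode %in% c("constant", "step_half_every_30"))
    return("decayMode must be 'constant' or 'step_half_every_30'")
  TRUE
})

#' Construct an OptimizerSchedule
#' @param initialLr initial learning rate.
#' @param decayMode "constant" or "step_half_every_30".
#' @param beta1,beta2,epsilon Adam constants.
#' @return An [OptimizerSchedule-class].
#' @export
optimizerSchedule <- function(initialLr = 1e-4,
                              decayMode = c("constant", "step_half_every_30"),
                              beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  new("OptimizerSchedule", initialLr = initialLr, beta1 = beta1,
      beta2 = beta2, epsilon = epsilon, decayMode = match.arg(decayMode))
}

#' Training configuration
#'
#' @slot epochs number of passes over the training split.
#' @slot batchSize minibatch size.
#' @slot inputSize (height, width), both divisible by 32.
#' @slot augmentationProfile "full", "pretraining" (scale + rotation only)
#'   or "off".
#' @slot seed RNG seed covering shuffling, augmentation and dropout.
#' @slot spec the [ModelSpec-class] to train.
#' @slot schedule the [OptimizerSchedule-class].
#' @slot augmentation the [AugmentationConfig-class] used when augmentation
#'   is enabled.
#' @export
setClass("TrainConfig", representation(
  epochs = "integer",
  batchSize = "integer",
  inputSize = "integer",
  augmentationProfile = "character",
  seed = "integer",
  spec = "ModelSpec",
  schedule = "OptimizerSchedule",
  augmentation = "AugmentationConfig"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (any(object@inputSize %% 32L != 0L))
    msg <- c(msg, "inputSize must be divisible by 32")
  if (!object@augmentationProfile %in% c("full", "pretraining", "off"))
    msg <- c(msg, "augmentationProfile must be full/pretraining/off")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param epochs training epochs (one pass over the split per epoch).
#' @param batchSize minibatch size.
#' @param inputSize c(height, width), divisible by 32.
#' @param augmentationProfile "full", "pretraining" or "off".
#' @param seed RNG seed.
#' @param spec model specification.
#' @param schedule optimizer schedule (default: Adam, lr 1e-4, constant).
#' @param augmentation augmentation configuration.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 150L, batchSize = 8L,
                        inputSize = c(96L, 96L),
                        augmentationProfile = c("off", "full", "pretraining"),
                        seed = 1L, spec = modelSpec("batchnorm"),
                        schedule = optimizerSchedule(),
                        augmentation = augmentationConfig()) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), inputSize = as.integer(inputSize),
      augmentationProfile = match.arg(augmentationProfile),
      seed = as.integer(seed), spec = spec, schedule = schedule,
      augmentation = augmentation)
}

#' Per-class segmentation metrics
#'
#' IoU = TP / (TP + FP + FN) and class-wise pixel accuracy (recall)
#' ACC = TP / (TP + FN) for the six foreground classes; means are arithmetic
#' means over the foreground classes present in prediction or truth.
#'
#' @slot perClass data.frame: class, iou, acc (NA when the class is absent
#'   from both masks).
#' @slot meanIoU,meanAcc means over the six foreground classes.
#' @export
setClass("MetricsTable", representation(
  perClass = "data.frame",
  meanIoU = "numeric",
  meanAcc = "numeric"
))

#' Synthetic neonate scene specification
#'
#' Describes a geometric-primitive "neonate" (large elliptical head,
#' rectangular torso, four limb bars) on a cluttered background, with
#' optional clothing occlusion, illumination gradient and NIR-style
#' underexposure. Canvas dimensions must be divisible by 32.
#'
#' @slot canvas integer (height, width).
#' @slot skinTone "light", "medium" or "dark".
#' @slot orientation "prone", "supine" or "side".
#' @slot occlusionFraction fraction of the torso covered by clothing.
#' @slot illumination "uniform" or "gradient".
#' @slot exposureScale intensity gain; < 1 emulates NIR underexposure.
#' @slot modality "RGB" or "NIR".
#' @slot layoutPreset "neonate" (large head) or "adult" (small head).
#' @slot seed scene RNG seed.
#' @export
setClass("SceneSpec", representation(
  canvas = "integer",
  skinTone = "character",
  orientation = "character",
  occlusionFraction = "numeric",
  illumination = "character",
  exposureScale = "numeric",
  modality = "character",
  layoutPreset = "character",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (any(object@canvas %% 32L != 0L))
    msg <- c(msg, sprintf("canvas dimensions must be divisible by 32 (got %s)",
                          paste(object@canvas, collapse = " x ")))
  if (!object@skinTone %in% c("light", "medium", "dark"))
    msg <- c(msg, "skinTone must be light/medium/dark")
  if (!object@orientation %in% c("prone", "supine", "side"))
    msg <- c(msg, "orientation must be prone/supine/side")
  if (object@occlusionFraction < 0 || object@occlusionFraction > 1)
    msg <- c(msg, "occlusionFraction must lie in [0, 1]")
  if (!object@modality %in% c("RGB", "NIR"))
    msg <- c(msg, "modality must be RGB or NIR")
  if (!object@illumination %in% c("uniform", "gradient"))
    msg <- c(msg, "illumination must be uniform or gradient")
  if (!object@layoutPreset %in% c("neonate", "adult"))
    msg <- c(msg, "layoutPreset must be neonate or adult")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#' @param canvas c(height, width), divisible by 32.
#' @param skinTone "light", "medium" or "dark".
#' @param orientation "prone", "supine" or "side".
#' @param occlusionFraction torso fraction covered by a clothing patch.
#' @param illumination "uniform" or "gradient".
#' @param exposureScale gain < 1 emulates underexposure.
#' @param modality "RGB" (3-channel) or "NIR" (1-channel).
#' @param layoutPreset "neonate" or "adult".
#' @param seed RNG seed.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(canvas = c(96L, 96L), skinTone = "medium",
                      orientation = "supine", occlusionFraction = 0.3,
                      illumination = "uniform", exposureScale = 1,
                      modality = "RGB", layoutPreset = "neonate", seed = 1L) {
  new("SceneSpec", canvas = as.integer(canvas), skinTone = skinTone,
      orientation = orientation,
      occlusionFraction = as.numeric(occlusionFraction),
      illumination = illumination, exposureScale = as.numeric(exposureScale),
      modality = modality, layoutPreset = layoutPreset,
      seed = as.integer(seed))
}
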