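# Joint image/mask augmentation.
#
# All operations keep the image and its label mask congruent: geometric
# transforms share one geometry, images are interpolated bilinearly, masks
# nearest-neighbor, and exposed canvas is black with background label. All
# random draws are uniform over the configured ranges.

.aug_state <- new.env(parent = emptyenv())
.aug_state$counters <- c(scale = 0L, rotate = 0L, flip = 0L, color = 0L)
.aug_state$warned_gray_saturation <- FALSE

bump_counter <- function(op) {
  .aug_state$counters[op] <- .aug_state$counters[op] + 1L
  invisible(NULL)
}

#' Augmentation operation counters
#'
#' Counts how often each augmentation operation has been applied in this
#' session; used to verify that training profiles invoke only the operations
#' they claim (the pre-training profile uses scaling and rotation only).
#'
#' @param reset if TRUE, zero the counters.
#' @return Named integer vector with counts for scale/rotate/flip/color.
#' @export
augCounters <- function(reset = FALSE) {
  if (reset) {
    .aug_state$counters <- c(scale = 0L, rotate = 0L, flip = 0L, color = 0L)
  }
  .aug_state$counters
}

as_image <- function(image) {
  im <- image
  if (length(dim(im)) == 2L) dim(im) <- c(dim(im), 1L)
  if (length(dim(im)) != 3L) stop("image must be (H, W) or (H, W, C)")
  im
}

check_congruent <- function(image, mask) {
  im <- as_image(image)
  lab <- maskLabels(mask)
  if (any(dim(im)[1:2] != dim(lab)))
    stop("image and mask dimensions differ")
  if (any(dim(im)[1:2] == 0L)) stop("degenerate (empty) image")
  im
}

#' Scale image and mask on a fixed-size canvas
#'
#' Resizes the content by `factor` (bilinear for the image, nearest-neighbor
#' for the mask) and returns a canvas of the original size: upscaled content
#' is cropped at the given origin, downscaled content is placed at the given
#' origin on a black background with background label filling the margin.
#'
#' @param image (H, W, C) or (H, W) array.
#' @param mask a [LabelMask-class].
#' @param factor positive scale factor.
#' @param originRow,originCol 1-based top-left crop/placement origin; NULL
#'   draws them uniformly.
#' @return list(image, mask).
#' @export
applyScale <- function(image, mask, factor, originRow = NULL,
                       originCol = NULL) {
  im <- check_congruent(image, mask)
  lab <- maskLabels(mask)
  d <- dim(im)
  H <- d[1]; W <- d[2]
  nh <- max(1L, as.integer(round(H * factor)))
  nw <- max(1L, as.integer(round(W * factor)))
  if (nh == H && nw == W)
    return(list(image = im, mask = labelMask(lab)))
  im4 <- array(im, dim = c(H, W, d[3], 1L))
  lab4 <- array(as.numeric(lab), dim = c(H, W, 1L, 1L))
  im_s <- nn_resize_bilinear_fw(im4, nh, nw)[, , , 1, drop = FALSE]
  lab_s <- nn_resize_nearest(lab4, nh, nw)[, , 1, 1]
  out_im <- array(0, dim = c(H, W, d[3]))
  out_lab <- matrix(0L, H, W)
  if (nh >= H) {  # crop
    r0 <- if (is.null(originRow)) sample.int(nh - H + 1L, 1L) else originRow
    c0 <- if (is.null(originCol)) sample.int(nw - W + 1L, 1L) else originCol
    out_im[, , ] <- im_s[r0:(r0 + H - 1L), c0:(c0 + W - 1L), , 1]
    out_lab[, ] <- lab_s[r0:(r0 + H - 1L), c0:(c0 + W - 1L)]
  } else {        # place on black background
    r0 <- if (is.null(originRow)) sample.int(H - nh + 1L, 1L) else originRow
    c0 <- if (is.null(originCol)) sample.int(W - nw + 1L, 1L) else originCol
    out_im[r0:(r0 + nh - 1L), c0:(c0 + nw - 1L), ] <- im_s[, , , 1]
    out_lab[r0:(r0 + nh - 1L), c0:(c0 + nw - 1L)] <- lab_s
  }
  list(image = out_im, mask = labelMask(out_lab))
}

#' @describeIn applyScale draw the factor uniformly from the config's
#'   scaleRange and a uniform crop/placement origin.
#' @param cfg an [AugmentationConfig-class].
#' @export
randomScale <- function(image, mask, cfg = augmentationConfig()) {
  bump_counter("scale")
  factor <- stats::runif(1, cfg@scaleRange[1], cfg@scaleRange[2])
  out <- applyScale(image, mask, factor)
  attr(out, "factor") <- factor
  out
}

#' Rotate image and mask about the canvas center
#'
#' Content is rotated counter-clockwise by `angle` degrees; the canvas size
#' is unchanged and exposed corners are filled black with background label.
#' The image is resampled bilinearly, the mask nearest-neighbor, with
#' identical geometry.
#'
#' @param image (H, W, C) or (H, W) array.
#' @param mask a [LabelMask-class].
#' @param angle rotation angle in degrees.
#' @return list(image, mask).
#' @export
applyRotation <- function(image, mask, angle) {
  im <- check_congruent(image, mask)
  lab <- maskLabels(mask)
  if (angle == 0)
    return(list(image = im, mask = labelMask(lab)))
  d <- dim(im)
  im4 <- array(im, dim = c(d, 1L))
  lab4 <- array(as.numeric(lab), dim = c(d[1], d[2], 1L, 1L))
  im_r <- nn_warp_rotate(im4, angle, FALSE)[, , , 1]
  lab_r <- nn_warp_rotate(lab4, angle, TRUE)[, , 1, 1]
  dim(im_r) <- d
  list(image = im_r, mask = labelMask(matrix(as.integer(lab_r), d[1], d[2])))
}

#' @describeIn applyRotation draw the angle uniformly from
#'   [-maxRotationDeg, maxRotationDeg].
#' @param cfg an [AugmentationConfig-class].
#' @export
randomRotation <- function(image, mask, cfg = augmentationConfig()) {
  bump_counter("rotate")
  angle <- stats::runif(1, -cfg@maxRotationDeg, cfg@maxRotationDeg)
  out <- applyRotation(image, mask, angle)
  attr(out, "angle") <- angle
  out
}

#' Mirror image and mask horizontally
#'
#' @param image (H, W, C) or (H, W) array.
#' @param mask a [LabelMask-class].
#' @param swapLabels if TRUE, left/right arm (4/3) and left/right leg (6/5)
#'   indices are exchanged; the clinical training runs left them unswapped.
#' @return list(image, mask).
#' @export
applyFlip <- function(image, mask, swapLabels = FALSE) {
  im <- check_congruent(image, mask)
  lab <- maskLabels(mask)
  W <- dim(im)[2]
  im_f <- im[, W:1, , drop = FALSE]
  lab_f <- lab[, W:1, drop = FALSE]
  if (swapLabels) {
    swap <- c(0L, 1L, 2L, 4L, 3L, 6L, 5L)
    lab_f <- matrix(swap[lab_f + 1L], nrow(lab_f), ncol(lab_f))
  }
  list(image = im_f, mask = labelMask(lab_f))
}

#' @describeIn applyFlip mirror with probability `flipProbability`.
#' @param cfg an [AugmentationConfig-class].
#' @export
randomFlip <- function(image, mask, cfg = augmentationConfig()) {
  bump_counter("flip")
  if (stats::runif(1) < cfg@flipProbability)
    applyFlip(image, mask, cfg@swapLeftRightLabels)
  else
    list(image = as_image(image), mask = mask)
}

#' Photometric jitter: brightness, contrast, saturation
#'
#' Brightness is a multiplicative gain, contrast scales the deviation from
#' the image mean (`out = mean + f * (in - mean)`), and saturation
#' interpolates toward the per-pixel gray value (channel mean). The output
#' is clipped to `[0, maxValue]`. The mask is untouched. On a 1-channel
#' image the saturation step is a no-op (noted once per session).
#'
#' @param image (H, W, C) array.
#' @param brightness,contrast,saturation multiplicative factors.
#' @param maxValue upper clip bound (1 for normalized, 255 for 8-bit data).
#' @return The jittered image.
#' @export
applyColorJitter <- function(image, brightness = 1, contrast = 1,
                             saturation = 1, maxValue = 1) {
  im <- as_image(image)
  gray_input <- dim(im)[3] == 1L
  if (gray_input && saturation != 1 && !.aug_state$warned_gray_saturation) {
    message("color jitter: saturation is a no-op on 1-channel images")
    .aug_state$warned_gray_saturation <- TRUE
  }
  im <- im * brightness
  mu <- mean(im)
  im <- mu + contrast * (im - mu)
  if (!gray_input && saturation != 1) {
    gray <- apply(im, c(1, 2), mean)
    im <- array(gray, dim = dim(im)) +
      saturation * (im - array(gray, dim = dim(im)))
  }
  clamp(im, 0, maxValue)
}

#' @describeIn applyColorJitter draw the three factors independently and
#'   uniformly from the config's colorRange.
#' @param cfg an [AugmentationConfig-class].
#' @export
colorJitter <- function(image, cfg = augmentationConfig(), maxValue = 1) {
  bump_counter("color")
  f <- stats::runif(3, cfg@colorRange[1], cfg@colorRange[2])
  applyColorJitter(image, f[1], f[2], f[3], maxValue)
}

#' Apply the full augmentation chain to one training sample
#'
#' Operations run in the fixed order scale, rotate, flip, color (geometric
#' before photometric), restricted to `cfg@enabledOps`. Draws come from the
#' current RNG state, so a fixed seed reproduces the augmentation exactly.
#'
#' @param image (H, W, C) array.
#' @param mask a [LabelMask-class].
#' @param cfg an [AugmentationConfig-class].
#' @return list(image, mask).
#' @export
augmentSample <- function(image, mask, cfg = augmentationConfig()) {
  s <- list(image = as_image(image), mask = mask)
  if ("scale" %in% cfg@enabledOps)
    s <- randomScale(s$image, s$mask, cfg)
  if ("rotate" %in% cfg@enabledOps)
    s <- randomRotation(s$image, s$mask, cfg)
  if ("flip" %in% cfg@enabledOps)
    s <- randomFlip(s$image, s$mask, cfg)
  if ("color" %in% cfg@enabledOps)
    s$image <- colorJitter(s$image, cfg)
  s
}

# augmentation profile -> config restriction
profile_config <- function(cfg, profile) {
  if (profile == "pretraining") {
    cfg@enabledOps <- intersect(cfg@enabledOps, c("scale", "rotate"))
  } else if (profile == "off") {
    cfg@enabledOps <- character()
  }
  cfg
}
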