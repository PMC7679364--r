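# Virtual-NIR synthesis by constrained histogram matching.
#
# Real NIR frames are monochrome and typically underexposed; annotated
# training data exists mostly as RGB. A virtual NIR image is the red
# channel of an RGB frame (spectrally closest to 940-nm NIR) pushed through
# a monotone intensity map T that makes its histogram resemble a real NIR
# reference frame of the same recording.
#
# T is fitted per source intensity k as the smallest target intensity j
# whose cumulative histogram reaches the source cumulative at k minus half
# the source histogram mass at k: the map tracks the source quantile from
# above, and the source cumulative may exceed the target cumulative at
# T(k) by at most half the source count at k (the classic constrained-
# matching tolerance). Since the tracked level cs(k) - hs(k)/2 =
# cs(k-1) + hs(k)/2 is nondecreasing in k, T is monotone by construction,
# and a feasible level always exists because the target cumulative ends
# at 1.

#' 256-bin intensity histogram of an 8-bit-scaled image
#'
#' @param image numeric array/matrix with values in [0, 1] (or 0..255 when
#'   `eightBit = TRUE`); a 3-channel image is reduced to its red channel.
#' @param eightBit set TRUE when the data is already on the 0..255 scale.
#' @return Integer vector of 256 bin counts for intensities 0..255.
#' @export
imageHistogram <- function(image, eightBit = FALSE) {
  x <- image
  if (!is.null(dim(x)) && length(dim(x)) == 3L && dim(x)[3] >= 3L)
    x <- x[, , 1]
  lev <- if (eightBit) as.integer(round(x)) else as.integer(round(x * 255))
  lev <- clamp(lev, 0L, 255L)
  tabulate(lev + 1L, nbins = 256L)
}

#' Fit a monotone histogram-matching intensity map
#'
#' Finds the 8-bit intensity map T that, per source intensity k, takes the
#' smallest target intensity whose cumulative histogram is no more than
#' half the (normalized) source histogram count at k below the source
#' cumulative at k. Equivalently: among maps respecting that half-count
#' tolerance, T minimizes the target cumulative per level, ties to the
#' smallest intensity, which makes it the unique minimizer of the summed
#' cumulative discrepancy among monotone tolerance-respecting maps.
#' Deterministic; monotone by construction.
#'
#' @param sourceHist,targetHist 256-bin counts (source: red channel of the
#'   RGB data; target: a real NIR reference frame).
#' @return A [HistogramMapping-class].
#' @export
#' @examples
#' h <- rep(1, 256)
#' fitHistogramMapping(h, h)  # identity on occupied bins
fitHistogramMapping <- function(sourceHist, targetHist) {
  if (length(sourceHist) != 256L || length(targetHist) != 256L)
    stop("histograms must have 256 bins")
  if (sum(sourceHist) <= 0) stop("source histogram is empty (all zero)")
  if (sum(targetHist) <= 0) stop("target histogram is empty (all zero)")
  hs <- sourceHist / sum(sourceHist)
  ht <- targetHist / sum(targetHist)
  cs <- cumsum(hs)
  ct <- cumsum(ht)
  tracked <- cs - hs / 2   # nondecreasing, so T is monotone
  map <- vapply(seq_len(256L), function(k)
    which(ct >= tracked[k] - 1e-12)[1] - 1L, integer(1))
  map <- as.integer(cummax(map))  # monotone by construction; enforce anyway
  new("HistogramMapping", sourceHist = as.numeric(sourceHist),
      targetHist = as.numeric(targetHist), sourceCdf = cs, targetCdf = ct,
      map = map)
}

#' @describeIn fitHistogramMapping the fitted intensity map as an integer
#'   vector `T` with `T[k + 1]` = T(k), k in 0..255.
#' @param mapping a [HistogramMapping-class].
#' @export
intensityMap <- function(mapping) mapping@map

#' Synthesize a virtual NIR image from an RGB frame
#'
#' Extracts the red channel and applies the fitted monotone intensity map
#' pixelwise. Label masks are untouched by construction (the transform is
#' purely photometric).
#'
#' @param rgb (H, W, 3) array with values in [0, 1].
#' @param target a [HistogramMapping-class], or a 256-bin target histogram
#'   (counts of the real NIR reference frame) from which the mapping is
#'   fitted against the image's own red-channel histogram.
#' @return (H, W) matrix in [0, 1]: the virtual NIR image.
#' @export
toVirtualNIR <- function(rgb, target) {
  if (is.null(dim(rgb)) || length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("expected a 3-channel RGB image")
  if (missing(target) || is.null(target))
    stop("a target NIR histogram is required: supply the 256-bin histogram ",
         "of one real NIR frame of the same recording ",
         "(imageHistogram(nirFrame))")
  red <- rgb[, , 1]
  mapping <- if (is(target, "HistogramMapping")) target
    else fitHistogramMapping(imageHistogram(red), target)
  lev <- clamp(as.integer(round(red * 255)), 0L, 255L)
  out <- mapping@map[lev + 1L] / 255
  matrix(out, nrow(red), ncol(red))
}

setMethod("show", "HistogramMapping", function(object) {
  cat("HistogramMapping: monotone 8-bit intensity map\n")
  cat("  range: T(0..255) in [", min(object@map), ", ", max(object@map),
      "]\n", sep = "")
})
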