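# Analytic parameter and FMA accounting.
#
# Counting convention (stated in every report header): a convolution costs
# k^2 * Cin * Cout * Hout * Wout multiply-adds with the bias folded into the
# accumulate; a transposed convolution is counted symmetrically over its
# input positions (k^2 * Cin * Cout * Hin * Win); fully connected layers
# cost fan_in * fan_out; normalization, activation, pooling, fixed bilinear
# interpolation and elementwise residual additions cost one FMA per output
# element; concatenation, dropout and the final softmax are free. One GFMA
# is 1e9 FMAs, reported rounded half-up to two decimals.

FMA_CONVENTION <- paste(
  "conv: k^2*Cin*Cout*Hout*Wout (bias folded);",
  "tconv: k^2*Cin*Cout*Hin*Win; fc: fan_in*fan_out;",
  "bn/relu/pool/interp/residual-add: 1 FMA per output element;",
  "concat/dropout/softmax: 0")

node_param_count <- function(nd) {
  switch(nd$kind,
    conv = nd$k^2 * nd$inC * nd$outC + if (isTRUE(nd$bias)) nd$outC else 0,
    tconv = nd$k^2 * nd$inC * nd$outC + nd$outC,
    bn = 2 * nd$channels,
    fc = nd$inF * nd$outF + nd$outF,
    0)
}

node_fma_count <- function(nd, out_shape, in_shape) {
  elems <- function(s) prod(as.numeric(s))
  switch(nd$kind,
    conv = nd$k^2 * as.numeric(nd$inC) * nd$outC * out_shape[1] * out_shape[2],
    tconv = nd$k^2 * as.numeric(nd$inC) * nd$outC * in_shape[1] * in_shape[2],
    fc = as.numeric(nd$inF) * nd$outF,
    bn = elems(out_shape),
    relu = elems(out_shape),
    maxpool = elems(out_shape),
    upsample = elems(out_shape),
    add = elems(out_shape),
    input = 0, concat = 0, dropout = 0, softmax = 0, flatten = 0,
    stop("FMA counting: unknown layer kind '", nd$kind, "' (layer '",
         nd$name, "')")
  )
}

as_nodes <- function(x) {
  if (is(x, "SegmentationNetwork")) x@nodes
  else if (is(x, "ModelSpec")) segnet_nodes(x)
  else if (is.list(x)) x
  else stop("expected a SegmentationNetwork, ModelSpec, or node list")
}

#' Count trainable parameters
#'
#' Counts every trainable array element: convolution and transposed
#' convolution weights and biases, affine normalization scale and shift,
#' fully connected weights and biases. Fixed bilinear upsampling kernels
#' are not trainable and are excluded. Parameter counts are independent of
#' the input size.
#'
#' @param x a [SegmentationNetwork-class], [ModelSpec-class], or node list
#'   (e.g. [vgg16Reference()]).
#' @param section restrict to "encoder", "decoder" or "head"; NULL = all.
#' @return Total parameter count (numeric scalar, exact integer value).
#' @export
#' @examples
#' countParameters(modelSpec("batchnorm"), section = "encoder")
countParameters <- function(x, section = NULL) {
  nodes <- as_nodes(x)
  if (!is.null(section))
    nodes <- Filter(function(nd) nd$section %in% section, nodes)
  sum(vapply(nodes, node_param_count, numeric(1)))
}

#' Count floating-point multiply-add operations per forward pass
#'
#' Analytic count at a given input size under the package's stated
#' convention (see [complexityReport()] for the header text). For full
#' segmentation networks the input must be divisible by 32.
#'
#' @param x a [SegmentationNetwork-class], [ModelSpec-class], or node list.
#' @param height,width input size in pixels.
#' @param section restrict to "encoder", "decoder" or "head"; NULL = all.
#' @return Total FMA count (numeric scalar).
#' @export
#' @examples
#' countFMAs(vgg16Reference(), 320, 320) / 1e9
countFMAs <- function(x, height, width, section = NULL) {
  nodes <- as_nodes(x)
  shapes <- infer_shapes(nodes, height, width)
  if (!is.null(section))
    keep <- vapply(nodes, function(nd) nd$section %in% section, logical(1))
  else keep <- rep(TRUE, length(nodes))
  total <- 0
  for (i in seq_along(nodes)) {
    if (!keep[i]) next
    nd <- nodes[[i]]
    in_shape <- if (length(nd$inputs)) shapes[[nd$inputs[1]]] else NULL
    total <- total + node_fma_count(nd, shapes[[nd$name]], in_shape)
  }
  total
}

#' Per-layer complexity report
#'
#' Tabulates parameters and FMAs for every layer at the given input size,
#' with encoder/decoder/head and whole-network rollups.
#'
#' @param x a [SegmentationNetwork-class], [ModelSpec-class], or node list.
#' @param height,width input size in pixels.
#' @return A [ComplexityReport-class].
#' @export
#' @examples
#' rep <- complexityReport(modelSpec("batchnorm"), 320, 320)
#' totalsTable(rep)
complexityReport <- function(x, height, width) {
  nodes <- as_nodes(x)
  shapes <- infer_shapes(nodes, height, width)
  chans <- function(nm) {
    s <- shapes[[nm]]
    if (length(s) == 3L) s else c(NA_integer_, NA_integer_, s)
  }
  pl <- do.call(rbind, lapply(nodes, function(nd) {
    s <- chans(nd$name)
    in_shape <- if (length(nd$inputs)) shapes[[nd$inputs[1]]] else NULL
    data.frame(name = nd$name, kind = nd$kind, section = nd$section,
               outH = s[1], outW = s[2], outC = s[3],
               params = node_param_count(nd),
               fmas = node_fma_count(nd, shapes[[nd$name]], in_shape),
               stringsAsFactors = FALSE)
  }))
  sect <- function(s) {
    rows <- pl[pl$section %in% s, ]
    data.frame(section = paste(s, collapse = "+"),
               params = sum(rows$params), fmas = sum(rows$fmas),
               gfmas = round_half_up(sum(rows$fmas) / 1e9, 2),
               stringsAsFactors = FALSE)
  }
  totals <- rbind(sect("encoder"), sect("decoder"), sect("head"),
                  data.frame(section = "total", params = sum(pl$params),
                             fmas = sum(pl$fmas),
                             gfmas = round_half_up(sum(pl$fmas) / 1e9, 2),
                             stringsAsFactors = FALSE))
  inC <- nodes[[1]]$channels
  new("ComplexityReport", perLayer = pl, totals = totals,
      inputSize = as.integer(c(height, width, inC)))
}

#' @describeIn complexityReport the per-layer table.
#' @param report a [ComplexityReport-class].
#' @export
perLayerTable <- function(report) report@perLayer

#' @describeIn complexityReport the rollup table (params, FMAs, GFMAs).
#' @export
totalsTable <- function(report) report@totals

#' Write a complexity report as a delimited text table
#'
#' @param report a [ComplexityReport-class].
#' @param path output file; tab-separated, with the counting convention and
#'   input size in `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
writeComplexityTable <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# input_size: ", paste(report@inputSize, collapse = "x")),
    paste0("# fma_convention: ", FMA_CONVENTION)), con)
  utils::write.table(report@perLayer, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

setMethod("show", "ComplexityReport", function(object) {
  cat("ComplexityReport at input ",
      paste(object@inputSize, collapse = " x "), "\n", sep = "")
  cat("# ", FMA_CONVENTION, "\n", sep = "")
  t <- object@totals
  t$params <- format(t$params, big.mark = ",")
  t$gfmas <- sprintf("%.2f", t$gfmas)
  print(t[, c("section", "params", "gfmas")], row.names = FALSE)
})
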