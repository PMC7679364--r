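# Layer-graph construction.
#
# A network architecture is an ordered list of nodes; each node is a list
# with at least: name, kind, inputs (names of predecessor nodes), section
# ("encoder", "decoder" or "head"). The list order is a topological order,
# so forward/backward passes and shape inference are simple sweeps.
#
# Node kinds: input, conv, tconv, bn, relu, maxpool, add, concat, upsample
# (fixed bilinear x2), dropout, softmax, flatten, fc (the last two only for
# auditing reference classifiers).

node_conv <- function(name, input, inC, outC, k, stride = 1L, pad = NULL,
                      bias = FALSE, section = "encoder") {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(name = name, kind = "conv", inputs = input, section = section,
       inC = as.integer(inC), outC = as.integer(outC), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), bias = bias)
}

node_tconv <- function(name, input, inC, outC, k = 4L, stride = 2L,
                       pad = 1L, section = "decoder") {
  list(name = name, kind = "tconv", inputs = input, section = section,
       inC = as.integer(inC), outC = as.integer(outC), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), bias = TRUE)
}

node_simple <- function(.name, .kind, .input, .section, ...) {
  c(list(name = .name, kind = .kind, inputs = .input, section = .section),
    list(...))
}

# conv [+ bn | dropout] + relu block, honoring the decoder variant
dec_conv_block <- function(nodes, name, input, inC, outC, k, variant,
                           dropoutRate) {
  nodes[[length(nodes) + 1L]] <-
    node_conv(name, input, inC, outC, k, bias = TRUE, section = "decoder")
  last <- name
  if (variant %in% c("batchnorm", "bilinear", "unconnected")) {
    nodes[[length(nodes) + 1L]] <-
      node_simple(paste0(name, "_bn"), "bn", last, "decoder", channels = outC)
    last <- paste0(name, "_bn")
  }
  nodes[[length(nodes) + 1L]] <-
    node_simple(paste0(name, "_relu"), "relu", last, "decoder")
  last <- paste0(name, "_relu")
  if (variant == "dropout") {
    nodes[[length(nodes) + 1L]] <-
      node_simple(paste0(name, "_drop"), "dropout", last, "decoder",
                  rate = dropoutRate)
  }
  nodes
}

# one ResNet bottleneck: 1x1 -> 3x3 (stride here) -> 1x1 (+ downsample)
bottleneck_nodes <- function(prefix, input, inC, midC, outC, stride,
                             downsample) {
  n <- list()
  add <- function(x) n[[length(n) + 1L]] <<- x
  add(node_conv(paste0(prefix, "_conv1"), input, inC, midC, 1L))
  add(node_simple(paste0(prefix, "_bn1"), "bn", paste0(prefix, "_conv1"),
                  "encoder", channels = midC))
  add(node_simple(paste0(prefix, "_relu1"), "relu", paste0(prefix, "_bn1"),
                  "encoder"))
  add(node_conv(paste0(prefix, "_conv2"), paste0(prefix, "_relu1"),
                midC, midC, 3L, stride = stride))
  add(node_simple(paste0(prefix, "_bn2"), "bn", paste0(prefix, "_conv2"),
                  "encoder", channels = midC))
  add(node_simple(paste0(prefix, "_relu2"), "relu", paste0(prefix, "_bn2"),
                  "encoder"))
  add(node_conv(paste0(prefix, "_conv3"), paste0(prefix, "_relu2"),
                midC, outC, 1L))
  add(node_simple(paste0(prefix, "_bn3"), "bn", paste0(prefix, "_conv3"),
                  "encoder", channels = outC))
  shortcut <- input
  if (downsample) {
    add(node_conv(paste0(prefix, "_ds"), input, inC, outC, 1L,
                  stride = stride))
    add(node_simple(paste0(prefix, "_dsbn"), "bn", paste0(prefix, "_ds"),
                    "encoder", channels = outC))
    shortcut <- paste0(prefix, "_dsbn")
  }
  add(node_simple(paste0(prefix, "_add"), "add",
                  c(paste0(prefix, "_bn3"), shortcut), "encoder"))
  add(node_simple(paste0(prefix, "_relu"), "relu", paste0(prefix, "_add"),
                  "encoder"))
  n
}

# modified ResNet-50: classification head removed, feature maps exposed at
# strides 2 (stem), 4, 8, 16, 32
resnet50_encoder_nodes <- function(inputChannels = 3L) {
  n <- list(node_simple("input", "input", character(), "encoder",
                        channels = as.integer(inputChannels)))
  add <- function(x) n[[length(n) + 1L]] <<- x
  add(node_conv("stem_conv", "input", inputChannels, 64L, 7L, stride = 2L,
                pad = 3L))
  add(node_simple("stem_bn", "bn", "stem_conv", "encoder", channels = 64L))
  add(node_simple("stem_relu", "relu", "stem_bn", "encoder"))
  add(node_simple("stem_pool", "maxpool", "stem_relu", "encoder",
                  k = 3L, stride = 2L, pad = 1L))
  cfg <- list(
    list(stage = "layer1", blocks = 3L, mid = 64L, out = 256L, stride = 1L),
    list(stage = "layer2", blocks = 4L, mid = 128L, out = 512L, stride = 2L),
    list(stage = "layer3", blocks = 6L, mid = 256L, out = 1024L, stride = 2L),
    list(stage = "layer4", blocks = 3L, mid = 512L, out = 2048L, stride = 2L)
  )
  input <- "stem_pool"
  inC <- 64L
  for (st in cfg) {
    for (b in seq_len(st$blocks)) {
      prefix <- paste0(st$stage, "_b", b)
      blk <- bottleneck_nodes(prefix, input, inC,
                              st$mid, st$out,
                              stride = if (b == 1L) st$stride else 1L,
                              downsample = b == 1L)
      for (x in blk) add(x)
      input <- paste0(prefix, "_relu")
      inC <- st$out
    }
  }
  n
}

# encoder tap points: stride -> (node name, channels)
encoder_taps <- function() {
  list(`2`  = list(name = "stem_relu",      channels = 64L),
       `4`  = list(name = "layer1_b3_relu", channels = 256L),
       `8`  = list(name = "layer2_b4_relu", channels = 512L),
       `16` = list(name = "layer3_b6_relu", channels = 1024L),
       `32` = list(name = "layer4_b3_relu", channels = 2048L))
}

# FCN-style decoder over the encoder taps. Per stage: x2 upsampling
# (transposed conv k4 s2, or fixed bilinear in the "bilinear" variant),
# concatenation with a 1x1-scored skip feature map (except "unconnected"),
# and a 3x3 fusion convolution. A final x2 upsampling restores the input
# resolution before the 1x1 classifier and softmax.
decoder_nodes <- function(spec) {
  v <- spec@decoderVariant
  w <- spec@decoderWidth
  taps <- encoder_taps()
  n <- list()
  add <- function(x) n[[length(n) + 1L]] <<- x
  up_block <- function(name, input) {
    if (v == "bilinear") {
      add(node_simple(name, "upsample", input, "decoder", factor = 2L,
                      channels = w))
      return(name)
    }
    add(node_tconv(name, input, w, w))
    last <- name
    if (v %in% c("batchnorm", "unconnected")) {
      add(node_simple(paste0(name, "_bn"), "bn", last, "decoder",
                      channels = w))
      last <- paste0(name, "_bn")
    }
    add(node_simple(paste0(name, "_relu"), "relu", last, "decoder"))
    paste0(name, "_relu")
  }
  n <- dec_conv_block(n, "score32", taps$`32`$name, taps$`32`$channels, w,
                      1L, v, spec@dropoutRate)
  last <- n[[length(n)]]$name
  for (s in c(16L, 8L, 4L, 2L)) {
    up <- up_block(paste0("up", s), last)
    if (v != "unconnected") {
      tap <- taps[[as.character(s)]]
      m0 <- length(n)
      n <- dec_conv_block(n, paste0("skip", s), tap$name, tap$channels, w,
                          1L, v, spec@dropoutRate)
      skip <- n[[length(n)]]$name
      add(node_simple(paste0("cat", s), "concat", c(up, skip), "decoder"))
      n <- dec_conv_block(n, paste0("fuse", s), paste0("cat", s), 2L * w, w,
                          3L, v, spec@dropoutRate)
    } else {
      n <- dec_conv_block(n, paste0("fuse", s), up, w, w, 3L, v,
                          spec@dropoutRate)
    }
    last <- n[[length(n)]]$name
  }
  last <- up_block("up_final", last)
  add(node_conv("classifier", last, w, spec@numClasses, 1L, bias = TRUE,
                section = "head"))
  add(node_simple("softmax", "softmax", "classifier", "head"))
  n
}

segnet_nodes <- function(spec) {
  c(resnet50_encoder_nodes(spec@inputChannels), decoder_nodes(spec))
}

#' Layer inventory of the unmodified VGG-16 classifier
#'
#' The standard 13-convolution VGG-16 with three fully connected layers,
#' used as a reference network for complexity audits. The first fully
#' connected layer is sized for the pool-5 output of the requested input
#' (e.g. 10 x 10 x 512 at a 320 x 320 input).
#'
#' @param inputSize c(height, width) of the audit input (default 320 x 320).
#' @return An ordered node list accepted by [countFMAs()] and
#'   [countParameters()].
#' @export
#' @examples
#' countParameters(vgg16Reference())
vgg16Reference <- function(inputSize = c(320L, 320L)) {
  n <- list(node_simple("input", "input", character(), "encoder",
                        channels = 3L))
  add <- function(x) n[[length(n) + 1L]] <<- x
  widths <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                 c(512L, 512L, 512L), c(512L, 512L, 512L))
  input <- "input"
  inC <- 3L
  for (s in seq_along(widths)) {
    for (i in seq_along(widths[[s]])) {
      nm <- sprintf("conv%d_%d", s, i)
      add(node_conv(nm, input, inC, widths[[s]][i], 3L, bias = TRUE))
      add(node_simple(paste0(nm, "_relu"), "relu", nm, "encoder"))
      input <- paste0(nm, "_relu")
      inC <- widths[[s]][i]
    }
    add(node_simple(sprintf("pool%d", s), "maxpool", input, "encoder",
                    k = 2L, stride = 2L, pad = 0L))
    input <- sprintf("pool%d", s)
  }
  pool5 <- as.integer(inputSize %/% 32L)
  feat <- prod(pool5) * 512L
  add(node_simple("flatten", "flatten", input, "head"))
  add(node_simple("fc6", "fc", "flatten", "head", inF = feat, outF = 4096L))
  add(node_simple("fc6_relu", "relu", "fc6", "head"))
  add(node_simple("fc7", "fc", "fc6_relu", "head", inF = 4096L,
                  outF = 4096L))
  add(node_simple("fc7_relu", "relu", "fc7", "head"))
  add(node_simple("fc8", "fc", "fc7_relu", "head", inF = 4096L,
                  outF = 1000L))
  n
}

# shape inference: returns list name -> c(H, W, C) (or c(F) after flatten)
infer_shapes <- function(nodes, height, width, channels = NULL) {
  shapes <- list()
  for (nd in nodes) {
    s <- switch(nd$kind,
      input = c(as.integer(height), as.integer(width),
                if (is.null(channels)) nd$channels else as.integer(channels)),
      conv = {
        i <- shapes[[nd$inputs]]
        c((i[1] + 2L * nd$pad - nd$k) %/% nd$stride + 1L,
          (i[2] + 2L * nd$pad - nd$k) %/% nd$stride + 1L, nd$outC)
      },
      tconv = {
        i <- shapes[[nd$inputs]]
        c((i[1] - 1L) * nd$stride - 2L * nd$pad + nd$k,
          (i[2] - 1L) * nd$stride - 2L * nd$pad + nd$k, nd$outC)
      },
      maxpool = {
        i <- shapes[[nd$inputs]]
        c((i[1] + 2L * nd$pad - nd$k) %/% nd$stride + 1L,
          (i[2] + 2L * nd$pad - nd$k) %/% nd$stride + 1L, i[3])
      },
      upsample = {
        i <- shapes[[nd$inputs]]
        c(i[1] * nd$factor, i[2] * nd$factor, i[3])
      },
      concat = {
        a <- shapes[[nd$inputs[1]]]
        b <- shapes[[nd$inputs[2]]]
        if (any(a[1:2] != b[1:2]))
          stop("concat '", nd$name, "': spatial shapes differ")
        c(a[1:2], a[3] + b[3])
      },
      add = {
        a <- shapes[[nd$inputs[1]]]
        b <- shapes[[nd$inputs[2]]]
        if (any(a != b)) stop("add '", nd$name, "': shapes differ")
        a
      },
      flatten = prod(shapes[[nd$inputs]]),
      fc = nd$outF,
      # bn, relu, dropout, softmax: shape-preserving
      shapes[[nd$inputs]]
    )
    shapes[[nd$name]] <- as.integer(s)
  }
  shapes
}
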