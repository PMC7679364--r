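# Building and running the encoder-decoder network.

# classic FCN bilinear-interpolation kernel for a stride-2, kernel-4
# transposed convolution
bilinear_kernel_1d <- function(k, factor) {
  center <- if (k %% 2 == 1) factor - 1 else factor - 0.5
  1 - abs(seq_len(k) - 1 - center) / factor
}

# Initialization gains. Batch normalization makes the forward pass
# invariant to each convolution's weight scale, but Adam's per-parameter
# step is capped near the learning rate, so the *relative* adaptation rate
# per step grows as initial weight norms shrink. Normalized layers
# therefore start at low gain; layers whose scale reaches the output
# directly (the classifier, and decoder convs in the dropout variant,
# which has no decoder normalization) use standard ReLU He gain.
GAIN2_ENCODER <- 1 / 8    # conv weight variance = gain^2 / fan_in
GAIN2_DECODER <- 1 / 50
GAIN2_HE <- 2

init_node_params <- function(nd, variant = "batchnorm") {
  switch(nd$kind,
    conv = {
      fan_in <- nd$k^2 * nd$inC
      gain2 <- if (nd$name == "classifier") GAIN2_HE
        else if (nd$section == "encoder") GAIN2_ENCODER
        else if (variant == "dropout") GAIN2_HE
        else GAIN2_DECODER
      W <- array(stats::rnorm(nd$k^2 * nd$inC * nd$outC,
                              sd = sqrt(gain2 / fan_in)),
                 dim = c(nd$k, nd$k, nd$inC, nd$outC))
      p <- list(W = W)
      if (isTRUE(nd$bias)) p$b <- numeric(nd$outC)
      p
    },
    tconv = {
      # bilinear identity initialization (standard FCN practice)
      f <- bilinear_kernel_1d(nd$k, nd$stride)
      W <- array(0, dim = c(nd$k, nd$k, nd$outC, nd$inC))
      for (c in seq_len(min(nd$inC, nd$outC)))
        W[, , c, c] <- outer(f, f)
      list(W = W, b = numeric(nd$outC))
    },
    bn = {
      # residual-final BN scales start at zero so each bottleneck begins
      # as the identity (zero-init residual)
      g <- if (grepl("_bn3$", nd$name)) 0 else 1
      list(gamma = rep(g, nd$channels), beta = numeric(nd$channels))
    },
    NULL
  )
}

#' Build a segmentation network from its specification
#'
#' Constructs the modified ResNet-50 encoder (classification head removed,
#' feature maps exposed at strides 2, 4, 8, 16 and 32) and the decoder in
#' the variant named by the spec. Weight initialization is deterministic
#' under the spec's `randomSeed`: low-gain Gaussian convolutions (see the
#' methods vignette for the gain rationale), bilinear-identity transposed
#' convolutions, zero-init residual batch normalization.
#'
#' @param spec a [ModelSpec-class].
#' @param encoderWeights optional path to an RDS file with a named list of
#'   encoder parameter arrays (a local pre-trained checkpoint). Required when
#'   `spec@usePretrainedEncoder` is TRUE; never downloaded.
#' @return A [SegmentationNetwork-class].
#' @export
#' @examples
#' net <- buildModel(modelSpec("batchnorm"))
#' countParameters(net, section = "encoder")
buildModel <- function(spec, encoderWeights = NULL) {
  validObject(spec)
  nodes <- segnet_nodes(spec)
  params <- list()
  buffers <- list()
  with_seed(spec@randomSeed, {
    for (nd in nodes) {
      p <- init_node_params(nd, spec@decoderVariant)
      if (!is.null(p)) params[[nd$name]] <- p
      if (nd$kind == "bn")
        buffers[[nd$name]] <- list(rm = numeric(nd$channels),
                                   rv = rep(1, nd$channels))
    }
  })
  net <- new("SegmentationNetwork", spec = spec, nodes = nodes,
             params = params, buffers = buffers)
  if (isTRUE(spec@usePretrainedEncoder)) {
    if (is.null(encoderWeights))
      stop("usePretrainedEncoder is set but no local encoder weights file ",
           "was supplied; pass encoderWeights = <path> (weights are never ",
           "downloaded and random initialization is not silently used)")
    net <- loadEncoderWeights(net, encoderWeights)
  }
  net
}

#' Load encoder weights from a local checkpoint
#'
#' The checkpoint is an RDS file holding a named list of parameter lists, as
#' written by [saveModel()] (its `params` element) or any list whose names
#' cover the encoder layers. If the network expects a single input channel
#' and the stored stem convolution has three, the RGB kernel is averaged
#' across the channel axis.
#'
#' @param net a [SegmentationNetwork-class].
#' @param path RDS file path.
#' @return The network with encoder parameters replaced.
#' @export
loadEncoderWeights <- function(net, path) {
  if (!file.exists(path))
    stop("encoder weights file not found: ", path)
  stored <- readRDS(path)
  if (!is.null(stored$params)) {
    if (!is.null(stored$buffers)) {
      for (nm in intersect(names(stored$buffers), names(net@buffers)))
        net@buffers[[nm]] <- stored$buffers[[nm]]
    }
    stored <- stored$params
  }
  enc_names <- vapply(Filter(function(nd) nd$section == "encoder" &&
                               nd$kind %in% c("conv", "bn"), net@nodes),
                      `[[`, character(1), "name")
  missing <- setdiff(enc_names, names(stored))
  if (length(missing))
    stop("encoder weights file lacks layers: ",
         paste(utils::head(missing, 5), collapse = ", "))
  for (nm in enc_names) {
    p <- stored[[nm]]
    if (nm == "stem_conv" && net@spec@inputChannels == 1L &&
        dim(p$W)[3] == 3L) {
      W <- apply(p$W, c(1, 2, 4), mean)
      p$W <- array(W, dim = c(dim(p$W)[1:2], 1L, dim(p$W)[4]))
    }
    net@params[[nm]] <- p
  }
  net
}

# ---- forward / backward executors -----------------------------------------

null_or <- function(x) if (is.null(x)) NULL else x

# forward sweep; returns list(outputs, caches, buffers)
run_forward <- function(net, x, training = FALSE, keep_all = FALSE) {
  nodes <- net@nodes
  params <- net@params
  buffers <- net@buffers
  outs <- new.env(parent = emptyenv())
  caches <- if (training) new.env(parent = emptyenv()) else NULL
  # consumer counts for memory release in inference mode
  consumers <- new.env(parent = emptyenv())
  if (!keep_all && !training) {
    for (nd in nodes) for (i in nd$inputs)
      assign(i, (if (exists(i, consumers)) get(i, consumers) else 0L) + 1L,
             consumers)
  }
  take <- function(nm) get(nm, envir = outs)
  for (nd in nodes) {
    y <- switch(nd$kind,
      input = (x - 0.5) / 0.25,
      conv = nn_conv_fw(take(nd$inputs), params[[nd$name]]$W,
                        null_or(params[[nd$name]]$b), nd$stride, nd$pad),
      tconv = nn_tconv_fw(take(nd$inputs), params[[nd$name]]$W,
                          params[[nd$name]]$b, nd$stride, nd$pad),
      bn = {
        p <- params[[nd$name]]
        bf <- buffers[[nd$name]]
        r <- nn_bn_fw(take(nd$inputs), p$gamma, p$beta, training,
                      bf$rm, bf$rv, 0.1, 1e-5)
        if (training) {
          buffers[[nd$name]] <- list(rm = r$rm, rv = r$rv)
          assign(nd$name, list(mean = r$mean, invstd = r$invstd), caches)
        }
        r$y
      },
      relu = nn_relu_fw_inplace(take(nd$inputs)),
      maxpool = {
        r <- nn_maxpool_fw(take(nd$inputs), nd$k, nd$stride, nd$pad)
        if (training) assign(nd$name, list(idx = r$idx), caches)
        r$y
      },
      add = take(nd$inputs[1]) + take(nd$inputs[2]),
      concat = {
        a <- take(nd$inputs[1]); b <- take(nd$inputs[2])
        da <- dim(a); db <- dim(b)
        y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
        y[, , seq_len(da[3]), ] <- a
        y[, , da[3] + seq_len(db[3]), ] <- b
        y
      },
      upsample = {
        d <- dim(take(nd$inputs))
        nn_resize_bilinear_fw(take(nd$inputs), d[1] * nd$factor,
                              d[2] * nd$factor)
      },
      dropout = {
        if (training) {
          mask <- array((stats::runif(length(take(nd$inputs))) >= nd$rate) /
                          (1 - nd$rate), dim = dim(take(nd$inputs)))
          assign(nd$name, list(mask = mask), caches)
          take(nd$inputs) * mask
        } else take(nd$inputs)
      },
      softmax = softmax_channels(take(nd$inputs)),
      stop("forward: unknown layer kind '", nd$kind, "'")
    )
    assign(nd$name, y, outs)
    if (!keep_all && !training) {
      for (i in nd$inputs) {
        left <- get(i, consumers) - 1L
        assign(i, left, consumers)
        if (left == 0L && i != "input") rm(list = i, envir = outs)
      }
    }
  }
  list(outputs = outs, caches = caches, buffers = buffers)
}

# channelwise softmax on an (H, W, C, N) array
softmax_channels <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- x
  for (n in seq_len(d[4])) {
    m <- matrix(x[, , , n], hw, d[3])
    mx <- m[cbind(seq_len(hw), max.col(m, ties.method = "first"))]
    e <- exp(m - mx)
    y[, , , n] <- e / rowSums(e)
  }
  y
}

# backward sweep from the classifier logits; returns named list of
# parameter gradients
run_backward <- function(net, x, fw, gradLogits) {
  nodes <- net@nodes
  params <- net@params
  outs <- fw$outputs
  caches <- fw$caches
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  assign("classifier", gradLogits, grads)
  acc <- function(nm, g) {
    if (exists(nm, grads)) assign(nm, get(nm, grads) + g, grads)
    else assign(nm, g, grads)
  }
  start <- which(vapply(nodes, `[[`, character(1), "name") == "classifier")
  take <- function(nm) if (nm == "input") (x - 0.5) / 0.25 else
    get(nm, envir = outs)
  for (j in rev(seq_len(start))) {
    nd <- nodes[[j]]
    if (!exists(nd$name, grads)) next
    gy <- get(nd$name, grads)
    switch(nd$kind,
      input = NULL,
      conv = {
        need_gx <- nd$inputs != "input"
        r <- nn_conv_bw(take(nd$inputs), params[[nd$name]]$W, gy,
                        nd$stride, nd$pad, isTRUE(nd$bias), need_gx)
        pgrads[[nd$name]] <- if (isTRUE(nd$bias))
          list(W = r$gw, b = r$gb) else list(W = r$gw)
        if (need_gx) acc(nd$inputs, r$gx)
      },
      tconv = {
        r <- nn_tconv_bw(take(nd$inputs), params[[nd$name]]$W, gy,
                         nd$stride, nd$pad)
        pgrads[[nd$name]] <- list(W = r$gw, b = r$gb)
        acc(nd$inputs, r$gx)
      },
      bn = {
        cc <- get(nd$name, caches)
        r <- nn_bn_bw(take(nd$inputs), gy, params[[nd$name]]$gamma,
                      cc$mean, cc$invstd)
        pgrads[[nd$name]] <- list(gamma = r$ggamma, beta = r$gbeta)
        acc(nd$inputs, r$gx)
      },
      relu = acc(nd$inputs, nn_relu_bw(get(nd$name, outs), gy)),
      maxpool = acc(nd$inputs,
                    nn_maxpool_bw(get(nd$name, caches)$idx, gy,
                                  dim(take(nd$inputs)))),
      add = { acc(nd$inputs[1], gy); acc(nd$inputs[2], gy) },
      concat = {
        ca <- dim(take(nd$inputs[1]))[3]
        acc(nd$inputs[1], gy[, , seq_len(ca), , drop = FALSE])
        acc(nd$inputs[2],
            gy[, , -seq_len(ca), , drop = FALSE])
      },
      upsample = {
        d <- dim(take(nd$inputs))
        acc(nd$inputs, nn_resize_bilinear_bw(gy, d[1], d[2]))
      },
      dropout = acc(nd$inputs, gy * get(nd$name, caches)$mask),
      stop("backward: unknown layer kind '", nd$kind, "'")
    )
    rm(list = nd$name, envir = grads)
  }
  pgrads
}

# validate and batch user images against the spec
prepare_batch <- function(net, images) {
  if (!is.list(images)) images <- list(images)
  imgs <- lapply(images, function(im) {
    im <- as_batch(im)[, , , 1, drop = FALSE]
    d <- dim(im)
    check_divisible32(d[1], d[2])
    want <- net@spec@inputChannels
    if (d[3] == 1L && want == 3L) {
      # monochrome/NIR input to an RGB network: replicate the channel
      im <- array(rep(im, 3L), dim = c(d[1], d[2], 3L, 1L))
    } else if (d[3] != want) {
      stop("channel mismatch: network expects ", want,
           " input channel(s), image has ", d[3])
    }
    im
  })
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) all(dim(i) == d1), logical(1))))
    stop("all images in a batch must share the same dimensions")
  x <- array(0, dim = c(d1[1], d1[2], d1[3], length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

#' Run a forward pass
#'
#' Evaluation-mode forward pass producing per-pixel class probabilities at
#' the input resolution. Input dimensions must be divisible by 32; a
#' single-channel image fed to a 3-channel network is replicated across
#' channels.
#'
#' @param net a [SegmentationNetwork-class].
#' @param images one image array (height x width x channels, values in
#'   [0, 1]) or a list of equally sized images.
#' @return A [ProbabilityMap-class], or a list of them for a list input.
#' @export
netForward <- function(net, images) {
  single <- !is.list(images)
  x <- prepare_batch(net, images)
  fw <- run_forward(net, x, training = FALSE)
  p <- get("softmax", fw$outputs)
  maps <- lapply(seq_len(dim(p)[4]), function(n)
    new("ProbabilityMap", probs = p[, , , n, drop = TRUE]))
  if (single) maps[[1]] else maps
}

#' Decode a probability map into a label mask
#'
#' Per-pixel argmax with ties broken toward the lowest class index (a
#' deterministic, background-favoring rule on degenerate outputs).
#'
#' @param probs a [ProbabilityMap-class] or an (H, W, C) probability array.
#' @return A [LabelMask-class] with 0-based class indices.
#' @export
predictMask <- function(probs) {
  p <- if (is(probs, "ProbabilityMap")) probs@probs else probs
  d <- dim(p)
  m <- matrix(p, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  labelMask(matrix(as.integer(lab), d[1], d[2]))
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS files holding the model spec (as metadata), all
#' parameters and the batch-normalization running statistics.
#'
#' @param net a [SegmentationNetwork-class].
#' @param path file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   reconstructed network.
#' @export
saveModel <- function(net, path) {
  saveRDS(list(specFields = list(
    decoderVariant = net@spec@decoderVariant,
    numClasses = net@spec@numClasses,
    inputChannels = net@spec@inputChannels,
    dropoutRate = net@spec@dropoutRate,
    decoderWidth = net@spec@decoderWidth,
    randomSeed = net@spec@randomSeed),
    params = net@params, buffers = net@buffers), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  f <- obj$specFields
  spec <- modelSpec(f$decoderVariant, numClasses = f$numClasses,
                    inputChannels = f$inputChannels,
                    dropoutRate = f$dropoutRate,
                    decoderWidth = f$decoderWidth, randomSeed = f$randomSeed)
  net <- buildModel(spec)
  net@params <- obj$params
  net@buffers <- obj$buffers
  net
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: decoder '", object@decoderVariant, "', ",
      object@numClasses, " classes, ", object@inputChannels,
      " input channel(s)\n", sep = "")
})

setMethod("show", "SegmentationNetwork", function(object) {
  cat("SegmentationNetwork (", object@spec@decoderVariant, " decoder)\n",
      sep = "")
  cat("  encoder parameters: ",
      format(countParameters(object, section = "encoder"), big.mark = ","),
      "\n  decoder+head parameters: ",
      format(countParameters(object) -
               countParameters(object, section = "encoder"),
             big.mark = ","), "\n", sep = "")
})
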