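test_that("model specs validate their configuration", {
  expect_error(modelSpec("resnet"), "unknown decoder variant")
  expect_error(modelSpec("batchnorm", numClasses = 1L), "numClasses")
  expect_error(modelSpec("batchnorm", inputChannels = 4L), "inputChannels")
  expect_error(modelSpec("dropout", dropoutRate = 1.5), "dropoutRate")
})

test_that("encoder parameter budget matches the modified ResNet-50 exactly", {
  for (v in c("bilinear", "unconnected", "dropout", "batchnorm"))
    expect_identical(countParameters(modelSpec(v), section = "encoder"),
                     23508032)
})

test_that("decoder variants differ only where they claim to", {
  arch <- function(v) neoseg:::segnet_nodes(modelSpec(v))
  dec_convs <- function(nodes) {
    d <- Filter(function(nd) nd$section != "encoder" &&
                  nd$kind %in% c("conv", "tconv"), nodes)
    sort(vapply(d, `[[`, character(1), "name"))
  }
  # dropout and batchnorm share the identical conv/tconv inventory
  expect_identical(dec_convs(arch("dropout")), dec_convs(arch("batchnorm")))
  # the extra layers are normalization vs dropout only
  kinds <- function(v) table(vapply(Filter(function(nd)
    nd$section == "decoder", arch(v)), `[[`, character(1), "kind"))
  kb <- kinds("batchnorm"); kd <- kinds("dropout")
  expect_false("dropout" %in% names(kb))
  expect_false("bn" %in% names(kd))
  # bilinear upsampling carries zero trainable parameters
  bl <- arch("bilinear")
  ups <- Filter(function(nd) nd$kind == "upsample", bl)
  expect_gt(length(ups), 0)
  expect_true(all(vapply(ups, neoseg:::node_param_count, numeric(1)) == 0))
  expect_lte(countParameters(modelSpec("bilinear"), "decoder"),
             countParameters(modelSpec("batchnorm"), "decoder"))
  # the unconnected decoder consumes no encoder taps beyond the deepest map
  un <- arch("unconnected")
  expect_false(any(vapply(un, function(nd) nd$kind == "concat", logical(1))))
  dec_inputs <- unlist(lapply(Filter(function(nd)
    nd$section != "encoder", un), `[[`, "inputs"))
  enc_taps <- setdiff(vapply(neoseg:::encoder_taps(), `[[`, character(1),
                             "name"), "layer4_b3_relu")
  expect_length(intersect(dec_inputs, enc_taps), 0)
})

test_that("a pretrained-encoder request without local weights fails loudly", {
  expect_error(
    buildModel(modelSpec("batchnorm", usePretrainedEncoder = TRUE)),
    "no local encoder weights")
  expect_error(
    buildModel(modelSpec("batchnorm", usePretrainedEncoder = TRUE),
               encoderWeights = tempfile()),
    "not found")
})

test_that("forward pass honors the resolution and softmax contracts", {
  net <- cached_net()
  set.seed(11)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- netForward(net, img)
  expect_s4_class(p, "ProbabilityMap")
  expect_equal(dim(p@probs), c(64L, 64L, 7L))
  sums <- rowSums(matrix(p@probs, 64 * 64, 7))
  expect_lt(max(abs(sums - 1)), 1e-5)
  # resolution contract at a second size
  p96 <- netForward(net, array(runif(96 * 96 * 3), c(96, 96, 3)))
  expect_equal(dim(p96@probs)[1:2], c(96L, 96L))
  # rejections name the offending dimension
  expect_error(netForward(net, array(0.5, c(100, 96, 3))),
               "height 100.*not divisible by 32")
  expect_error(netForward(net, array(0.5, c(96, 100, 3))),
               "width 100.*not divisible by 32")
})

test_that("channel handling: replication for mono input, mismatch rejected", {
  net <- cached_net()
  mono <- array(runif(64 * 64), c(64, 64, 1))
  p <- netForward(net, mono)
  expect_equal(dim(p@probs), c(64L, 64L, 7L))
  rgb3 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  net1 <- buildModel(modelSpec("batchnorm", inputChannels = 1L))
  expect_equal(dim(net1@params$stem_conv$W)[3], 1L)
  expect_error(netForward(net1, rgb3), "channel mismatch")
  p1 <- netForward(net1, mono)
  expect_equal(dim(p1@probs), c(64L, 64L, 7L))
})

test_that("evaluation-mode forward is deterministic", {
  net <- cached_net()
  set.seed(12)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  m1 <- maskLabels(predictMask(netForward(net, img)))
  m2 <- maskLabels(predictMask(netForward(net, img)))
  expect_identical(m1, m2)
  # and initialization is deterministic under the spec seed
  w1 <- buildModel(modelSpec("batchnorm", randomSeed = 5L))@params$stem_conv$W
  w2 <- buildModel(modelSpec("batchnorm", randomSeed = 5L))@params$stem_conv$W
  expect_identical(w1, w2)
})

test_that("argmax decoding matches a per-pixel scan and breaks ties low", {
  # one-hot pixel
  p <- array(0, c(2, 2, 7)); p[, , 4] <- 1
  expect_true(all(maskLabels(predictMask(p)) == 3L))
  # uniform probabilities: lowest-index tie-break -> background
  u <- array(1 / 7, c(3, 3, 7))
  expect_true(all(maskLabels(predictMask(u)) == 0L))
  # random maps vs exhaustive per-pixel maximum scan
  set.seed(13)
  for (rep in 1:5) {
    raw <- array(runif(6 * 5 * 7), c(6, 5, 7))
    pm <- raw / array(rep(apply(raw, c(1, 2), sum), 7), dim(raw))
    got <- maskLabels(predictMask(pm))
    for (i in 1:6) for (j in 1:5) {
      v <- pm[i, j, ]
      expect_identical(got[i, j], which(v == max(v))[1] - 1L)
    }
  }
})

test_that("checkpoints round-trip the spec and weights", {
  net <- cached_net()
  path <- tempfile(fileext = ".rds")
  saveModel(net, path)
  back <- loadModel(path)
  expect_identical(back@spec@decoderVariant, "batchnorm")
  expect_identical(back@params$stem_conv$W, net@params$stem_conv$W)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(netForward(back, img)@probs, netForward(net, img)@probs)
  # encoder weights load into a mono-input network by channel averaging
  net1 <- buildModel(modelSpec("batchnorm", inputChannels = 1L,
                               usePretrainedEncoder = TRUE),
                     encoderWeights = path)
  expect_equal(net1@params$stem_conv$W[, , 1, ],
               apply(net@params$stem_conv$W, c(1, 2, 4), mean),
               tolerance = 1e-12)
  unlink(path)
})

test_that("every decoder variant runs forward and takes optimizer steps", {
  ds <- small_scene_set(1)
  img <- ds[[1]]$image
  for (v in c("bilinear", "unconnected", "dropout")) {
    cfg <- trainConfig(epochs = 2L, batchSize = 1L, inputSize = c(64L, 64L),
                       augmentationProfile = "off", seed = 4L,
                       spec = modelSpec(v, randomSeed = 4L))
    fit <- trainModel(ds, cfg)
    expect_true(all(is.finite(fit$log$loss)))
    p <- netForward(fit$net, img)
    expect_equal(dim(p@probs), c(64L, 64L, 7L))
    sums <- rowSums(matrix(p@probs, 64 * 64, 7))
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
})
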