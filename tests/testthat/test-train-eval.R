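test_that("the learning-rate schedule halves every 30 epochs in step mode", {
  stepper <- optimizerSchedule(decayMode = "step_half_every_30")
  expect_identical(learningRate(stepper, 0), 1e-4)
  expect_identical(learningRate(stepper, 29), 1e-4)
  expect_identical(learningRate(stepper, 30), 5e-5)
  expect_identical(learningRate(stepper, 60), 2.5e-5)
  flat <- optimizerSchedule(decayMode = "constant")
  expect_identical(learningRate(flat, 100), 1e-4)
  expect_error(learningRate(flat, -1), ">= 0")
})

test_that("pixel cross-entropy has its closed forms and matches hand sums", {
  onehot <- array(0, c(2, 2, 7))
  truth <- labelMask(matrix(c(0L, 3L, 5L, 6L), 2, 2))
  for (i in 1:2) for (j in 1:2)
    onehot[i, j, maskLabels(truth)[i, j] + 1] <- 1
  expect_equal(pixelCrossEntropy(onehot, truth), 0)
  uni <- array(1 / 7, c(3, 3, 7))
  expect_equal(pixelCrossEntropy(uni, labelMask(matrix(2L, 3, 3))), log(7),
               tolerance = 1e-12)
  # random probabilities on a 3x3 mask vs the explicit per-pixel sum
  set.seed(41)
  raw <- array(runif(3 * 3 * 7), c(3, 3, 7))
  probs <- raw / array(rep(apply(raw, c(1, 2), sum), 7), dim(raw))
  t2 <- random_mask(3, 3)
  hand <- 0
  for (i in 1:3) for (j in 1:3)
    hand <- hand - log(probs[i, j, maskLabels(t2)[i, j] + 1])
  expect_equal(pixelCrossEntropy(probs, t2), hand / 9, tolerance = 1e-6)
  expect_error(pixelCrossEntropy(uni, labelMask(matrix(0L, 2, 2))),
               "shapes differ")
})

test_that("IoU and accuracy reproduce hand-enumerated confusion ratios", {
  ident <- random_mask(8, 8)
  m <- evaluateMasks(ident, ident)
  present <- perClassMetrics(m)
  expect_true(all(present$iou[!is.na(present$iou)] == 1))
  expect_true(all(present$acc[!is.na(present$acc)] == 1))
  expect_equal(meanIoU(m), 1)
  expect_equal(meanAcc(m), 1)
  # disjoint prediction and truth for a class: IoU 0, ACC 0
  t <- labelMask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  p <- labelMask(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  md <- perClassMetrics(evaluateMasks(p, t))
  expect_equal(md$iou[md$class == "head"], 0)
  expect_equal(md$acc[md$class == "head"], 0)
  # the 2x2 worked example: truth [head, head; torso, bg],
  # pred [head, torso; torso, bg]
  truth <- labelMask(matrix(c(1L, 2L, 1L, 0L), 2, 2))
  pred <- labelMask(matrix(c(1L, 2L, 2L, 0L), 2, 2))
  mw <- perClassMetrics(evaluateMasks(pred, truth))
  expect_equal(mw$iou[mw$class == "head"], 1 / 2)
  expect_equal(mw$acc[mw$class == "head"], 1 / 2)
  expect_equal(mw$iou[mw$class == "torso"], 1 / 2)
  expect_equal(mw$acc[mw$class == "torso"], 1)
})

test_that("metrics match a brute-force counter on random masks and IoU <= ACC", {
  set.seed(43)
  for (rep in 1:25) {
    p <- random_mask(8, 8)
    t <- random_mask(8, 8)
    got <- perClassMetrics(evaluateMasks(p, t))
    bf <- bf_metrics(p, t)
    expect_equal(got$iou, bf$iou)
    expect_equal(got$acc, bf$acc)
    ok <- !is.na(bf$iou) & !is.na(bf$acc)
    expect_true(all(got$iou[ok] <= got$acc[ok] + 1e-12))
  }
  # absent-everywhere classes are excluded from the means
  t0 <- labelMask(matrix(c(0L, 1L), 2, 2))
  m0 <- evaluateMasks(t0, t0)
  expect_true(is.na(perClassMetrics(m0)$iou[3]))
  expect_equal(meanIoU(m0), 1)
})

test_that("metrics accumulate over an image set before the ratio", {
  # half-right on one image, half-wrong on another: pooled, not averaged
  t1 <- labelMask(matrix(1L, 2, 2)); p1 <- labelMask(matrix(1L, 2, 2))
  t2 <- labelMask(matrix(1L, 2, 2)); p2 <- labelMask(matrix(0L, 2, 2))
  m <- perClassMetrics(evaluateMasks(list(p1, p2), list(t1, t2)))
  expect_equal(m$acc[m$class == "head"], 0.5)   # 4 of 8 truth pixels hit
})

small_cfg <- function(epochs, seed = 1L, n = 2L)
  trainConfig(epochs = epochs, batchSize = n, inputSize = c(64L, 64L),
              augmentationProfile = "off", seed = seed,
              spec = modelSpec("batchnorm", randomSeed = 2L))

test_that("training is reproducible and reduces the loss", {
  ds <- small_scene_set(2)
  f1 <- trainModel(ds, small_cfg(3L))
  f2 <- trainModel(ds, small_cfg(3L))
  expect_identical(f1$log$loss, f2$log$loss)
  f <- trainModel(ds, small_cfg(12L))
  expect_lt(f$log$loss[12], f$log$loss[1])
  # the per-epoch log records the schedule
  expect_true(all(f$log$lr == 1e-4))
  expect_error(trainModel(list(), small_cfg(1L)), "empty dataset")
  bad <- small_scene_set(1, canvas = c(32L, 32L))
  expect_error(trainModel(bad, small_cfg(1L)), "does not match")
})

test_that("the pretraining profile never invokes flip or color ops", {
  ds <- small_scene_set(2)
  cfg <- trainConfig(epochs = 2L, batchSize = 2L, inputSize = c(64L, 64L),
                     augmentationProfile = "pretraining", seed = 3L,
                     spec = modelSpec("batchnorm", randomSeed = 2L))
  augCounters(reset = TRUE)
  invisible(trainModel(ds, cfg))
  counts <- augCounters()
  expect_gt(counts[["scale"]], 0)
  expect_gt(counts[["rotate"]], 0)
  expect_identical(counts[["flip"]], 0L)
  expect_identical(counts[["color"]], 0L)
})

test_that("cross-validation holds out whole recordings and flags leakage", {
  ds <- c(small_scene_set(2, seed0 = 10L), small_scene_set(2, seed0 = 20L))
  ds[[1]]$recordingId <- "recA"; ds[[2]]$recordingId <- "recA"
  ds[[3]]$recordingId <- "recB"; ds[[4]]$recordingId <- "recB"
  folds <- c(recA = 1L, recB = 2L)
  cv <- crossValidate(ds, folds, small_cfg(2L))
  expect_length(cv$perFold, 2)
  expect_identical(cv$summary$metric, c("meanIoU", "meanAcc"))
  expect_true(all(cv$summary$min <= cv$summary$mean + 1e-12))
  expect_true(all(cv$summary$mean <= cv$summary$max + 1e-12))
  # a corrupted fold map (one recording in two folds) is a hard error
  leaky <- c(recA = 1L, recA = 2L, recB = 2L)
  expect_error(crossValidate(ds, leaky, small_cfg(1L)),
               "grouping invariant")
  expect_error(crossValidate(ds, c(recA = 1L), small_cfg(1L)),
               "missing from the fold map")
})

test_that("a deliberately underexposed recording evaluates worst", {
  mk <- function(id, seeds, expo) lapply(seeds, function(s) {
    sc <- generateScene(sceneSpec(canvas = c(64L, 64L), seed = s,
                                  exposureScale = expo,
                                  occlusionFraction = 0))
    list(image = sc$image, mask = sc$mask, recordingId = id)
  })
  ds <- c(mk("easy1", 1:2, 1), mk("easy2", 3:4, 1), mk("dark", 5:6, 0.02))
  folds <- c(easy1 = 1L, easy2 = 2L, dark = 3L)
  cv <- crossValidate(ds, folds, small_cfg(40L, n = 4L))
  ious <- vapply(cv$perFold, meanIoU, numeric(1))
  expect_identical(which.min(ious), 3L)
  expect_equal(cv$summary$min[1], ious[3])
})
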