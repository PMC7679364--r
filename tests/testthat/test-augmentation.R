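base_sample <- function(h = 40, w = 40) {
  set.seed(123)
  img <- array(runif(h * w * 3), c(h, w, 3))
  lab <- matrix(0L, h, w)
  lab[(h %/% 4):(h %/% 2), (w %/% 3):(w %/% 2)] <- 2L
  lab[max(1, h %/% 8):(h %/% 5), (w %/% 3):(w %/% 2)] <- 1L
  list(image = img, mask = labelMask(lab))
}

test_that("scaling: identity factor, fixed geometry, black-background fill", {
  s <- base_sample()
  out <- applyScale(s$image, s$mask, 1.0)
  expect_identical(out$image, s$image)
  expect_identical(maskLabels(out$mask), maskLabels(s$mask))
  # factor 0.7 at forced top-left placement: content confined to 1..28
  s2 <- base_sample()
  out <- applyScale(s2$image, s2$mask, 0.7, originRow = 1L, originCol = 1L)
  expect_equal(dim(out$image)[1:2], c(40L, 40L))
  expect_true(all(out$image[29:40, , ] == 0))
  expect_true(all(out$image[, 29:40, ] == 0))
  expect_true(all(maskLabels(out$mask)[29:40, ] == 0L))
  expect_true(all(maskLabels(out$mask)[, 29:40] == 0L))
  # the placed block is the nearest-neighbor downscale of the mask
  lab28 <- neoseg:::nn_resize_nearest(
    array(as.numeric(maskLabels(s2$mask)), c(40, 40, 1, 1)), 28L, 28L)
  expect_identical(maskLabels(out$mask)[1:28, 1:28],
                   matrix(as.integer(lab28), 28, 28))
  # upscaling crops to the canvas
  out <- applyScale(s2$image, s2$mask, 1.4, originRow = 3L, originCol = 5L)
  expect_equal(dim(out$image)[1:2], c(40L, 40L))
  expect_error(applyScale(array(0, c(0, 4, 3)),
                          labelMask(matrix(integer(), 0, 4)), 1),
               "degenerate")
})

test_that("the scale sampler is uniform on [0.7, 1.4]", {
  s <- base_sample(8, 8)
  set.seed(2024)
  factors <- replicate(1000,
    attr(randomScale(s$image, s$mask), "factor"))
  expect_gte(mean(factors), 1.0)   # uniform mean is 1.05
  expect_lte(mean(factors), 1.1)
  expect_gte(min(factors), 0.7)
  expect_lte(max(factors), 1.4)
})

test_that("rotation: identity at zero, shared geometry, bounded angles", {
  s <- base_sample()
  out <- applyRotation(s$image, s$mask, 0)
  expect_identical(out$image, s$image)
  # image and mask stay congruent: rotating the label plane as an image
  # with nearest-neighbor sampling reproduces the rotated mask
  lab_img <- array(as.numeric(maskLabels(s$mask)), c(40, 40, 1, 1))
  rot_lab <- neoseg:::nn_warp_rotate(lab_img, 17, TRUE)[, , 1, 1]
  out <- applyRotation(s$image, s$mask, 17)
  expect_identical(maskLabels(out$mask),
                   matrix(as.integer(rot_lab), 40, 40))
  # no class indices are invented
  expect_true(all(maskLabels(out$mask) %in%
                    unique(as.integer(maskLabels(s$mask)))))
  set.seed(7)
  ang <- replicate(300, attr(randomRotation(s$image, s$mask,
    augmentationConfig()), "angle"))
  expect_true(all(abs(ang) <= 30))
})

test_that("rotating a centered disk +30 then -30 preserves interior labels", {
  h <- 41
  rowg <- matrix(seq_len(h), h, h)
  colg <- t(rowg)
  r2 <- (rowg - 21)^2 + (colg - 21)^2
  lab <- matrix(0L, h, h)
  lab[r2 <= 15^2] <- 1L
  img <- array(lab / 2, c(h, h, 1))
  a <- applyRotation(img, labelMask(lab), 30)
  b <- applyRotation(a$image, a$mask, -30)
  interior <- r2 <= 13^2  # away from the pixelated rim
  expect_identical(maskLabels(b$mask)[interior], lab[interior])
})

test_that("flipping: involution, left/right label policy", {
  s <- base_sample()
  lab <- maskLabels(s$mask)
  lab[15:18, 2:8] <- 4L   # a left-arm region
  s$mask <- labelMask(lab)
  once <- applyFlip(s$image, s$mask)
  twice <- applyFlip(once$image, once$mask)
  expect_identical(twice$image, s$image)
  expect_identical(maskLabels(twice$mask), maskLabels(s$mask))
  # default: the mirrored region keeps the "left arm" label
  expect_identical(sort(unique(as.integer(maskLabels(once$mask)))),
                   sort(unique(as.integer(lab))))
  expect_true(all(maskLabels(once$mask)[15:18, 33:39] == 4L))
  # with swapping on it becomes "right arm"
  swapped <- applyFlip(s$image, s$mask, swapLabels = TRUE)
  expect_true(all(maskLabels(swapped$mask)[15:18, 33:39] == 3L))
})

test_that("color jitter follows its stated brightness/contrast/saturation model", {
  img <- array(0.4, c(6, 6, 3))
  expect_identical(applyColorJitter(img, 1, 1, 1), img)
  # brightness on the 8-bit scale: constant 100 -> constant 110
  i100 <- array(100, c(4, 4, 3))
  expect_true(all(abs(applyColorJitter(i100, brightness = 1.1,
                                       maxValue = 255) - 110) < 1e-12))
  # contrast 0.9: pixel 150 with image mean 100 -> 145
  i2 <- array(c(50, 150), c(2, 1, 3))
  out <- applyColorJitter(i2, contrast = 0.9, maxValue = 255)
  expect_equal(out[2, 1, 1], 145)
  expect_equal(out[1, 1, 1], 55)
  # saturation pulls channels toward the per-pixel gray
  i3 <- array(c(0.2, 0.5, 0.8), c(1, 1, 3))
  out <- applyColorJitter(i3, saturation = 0.5)
  expect_equal(as.numeric(out), 0.5 + 0.5 * (c(0.2, 0.5, 0.8) - 0.5))
  # output is clipped to the valid range
  expect_true(all(applyColorJitter(array(0.99, c(2, 2, 3)),
                                   brightness = 1.1) <= 1))
  # saturation on a 1-channel image: explicit no-op, noted once
  aug_state <- neoseg:::.aug_state
  aug_state$warned_gray_saturation <- FALSE
  mono <- array(0.3, c(3, 3, 1))
  expect_message(applyColorJitter(mono, saturation = 1.1), "no-op")
  expect_silent(out2 <- applyColorJitter(mono, saturation = 1.1))
  expect_identical(out2, mono)
})

test_that("the augmentation chain is reproducible and honors profiles", {
  s <- base_sample()
  cfg <- augmentationConfig()
  a1 <- with(list(), { set.seed(31); augmentSample(s$image, s$mask, cfg) })
  a2 <- with(list(), { set.seed(31); augmentSample(s$image, s$mask, cfg) })
  expect_identical(a1$image, a2$image)
  expect_identical(maskLabels(a1$mask), maskLabels(a2$mask))
  # masks never acquire out-of-alphabet values
  expect_true(all(maskLabels(a1$mask) %in% 0:6))
  # the pretraining profile drops flip and color
  pre <- neoseg:::profile_config(cfg, "pretraining")
  expect_identical(sort(pre@enabledOps), c("rotate", "scale"))
  off <- neoseg:::profile_config(cfg, "off")
  expect_length(off@enabledOps, 0)
})
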