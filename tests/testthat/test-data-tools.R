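test_that("mask PNG round trips are lossless over the palette", {
  bg <- labelMask(matrix(0L, 6, 7))
  p <- tempfile(fileext = ".png")
  writeMask(bg, p)
  expect_identical(maskLabels(readMask(p)), maskLabels(bg))
  set.seed(21)
  for (rep in 1:3) {
    m <- random_mask(12, 9)
    writeMask(m, p)
    expect_identical(maskLabels(readMask(p)), maskLabels(m))
  }
  # a color outside the palette is rejected with the offending color
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- 0.5   # mid gray-red, not a class color
  png::writePNG(img, p)
  expect_error(readMask(p), "outside the class palette.*#800000")
  unlink(p)
})

test_that("keyframe ranking follows motion magnitude", {
  still <- replicate(5, matrix(0.5, 16, 16), simplify = FALSE)
  expect_warning(sel <- selectKeyframes(still, 2), "0 of 2")
  expect_length(sel, 0)
  # one frame shifts a bright block: that transition ranks first
  frames <- replicate(6, matrix(0, 16, 16), simplify = FALSE)
  for (i in seq_along(frames)) frames[[i]][4:8, 4:8] <- 1
  frames[[4]][, ] <- 0
  frames[[4]][4:8, 10:14] <- 1   # moved block at frame 4
  sel <- selectKeyframes(frames, 1)
  expect_identical(sel[1], 4L)
  # injected magnitudes order the selection; scores match per-pixel sums
  seqd <- generateSequence(sceneSpec(canvas = c(64L, 64L), seed = 3L),
                           nFrames = 4, motionSchedule = c(9, 5, 2))
  sel <- selectKeyframes(seqd$frames, 3, minGap = 1L)
  scores <- attr(sel, "scores")
  bf <- vapply(1:3, function(t)
    sum(abs(seqd$frames[[t + 1]] - seqd$frames[[t]])) /
      length(seqd$frames[[t]]), numeric(1))
  expect_equal(scores, bf, tolerance = 1e-12)
  expect_identical(sel, structure(c(2L, 3L, 4L), scores = scores))
  # a minimum gap suppresses adjacent picks
  sel2 <- suppressWarnings(selectKeyframes(seqd$frames, 3, minGap = 2L))
  expect_identical(as.integer(sel2), c(2L, 4L))
})

test_that("keyframe scoring is direction-consistent under reversal", {
  seqd <- generateSequence(sceneSpec(canvas = c(64L, 64L), seed = 4L),
                           nFrames = 5, motionSchedule = c(8, 1, 6, 2))
  f <- selectKeyframes(seqd$frames, 1)
  r <- selectKeyframes(rev(seqd$frames), 1)
  expect_identical(attr(f, "scores"), rev(attr(r, "scores")))
})

equal_cohort <- function(n, frames = 10L) {
  data.frame(recording_id = sprintf("r%02d", seq_len(n)),
             subject_origin = "European", orientation = "supine",
             modality = "RGB", frames = frames,
             stringsAsFactors = FALSE)
}

test_that("fold assignment balances homogeneous cohorts exactly", {
  f5 <- assignFolds(equal_cohort(5), k = 5)
  expect_identical(sort(unname(foldOf(f5))), 1:5)
  f10 <- assignFolds(equal_cohort(10), k = 5)
  counts <- table(foldOf(f10))
  expect_true(all(counts == 2))
  frames_per_fold <- tapply(rep(10L, 10), foldOf(f10), sum)
  expect_true(all(frames_per_fold == 20L))
  expect_error(assignFolds(equal_cohort(3), k = 5), "exceed")
})

test_that("greedy fold balancing attains the enumerated optimum on a small instance", {
  rec <- equal_cohort(6)
  rec$frames <- c(37L, 25L, 18L, 12L, 9L, 4L)
  got <- assignFolds(rec, k = 3)
  got_cost <- foldBalanceCost(rec, foldOf(got), 3)
  all_costs <- apply(expand.grid(rep(list(1:3), 6)), 1, function(a) {
    fo <- as.integer(a); names(fo) <- rec$recording_id
    foldBalanceCost(rec, fo, 3)
  })
  expect_lte(got_cost, min(all_costs) + 1e-9)
})

test_that("the grouping invariant holds for every assignment", {
  set.seed(33)
  for (rep in 1:20) {
    co <- generateCohort(sample(6:20, 1), sample(2:8, 1), seed = rep,
                         renderFrames = FALSE)
    k <- sample(2:5, 1)
    f <- assignFolds(co$records, k = k)
    fo <- foldOf(f)
    expect_false(anyDuplicated(names(fo)) > 0)
    expect_setequal(names(fo), unique(co$records$recording_id))
    expect_true(all(fo >= 1 & fo <= k))
    # fold is a function of recording id alone
    per_frame <- fo[co$records$recording_id]
    expect_true(all(tapply(per_frame, co$records$recording_id,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("fold CSVs round trip", {
  f <- assignFolds(equal_cohort(7), k = 3)
  p <- tempfile(fileext = ".csv")
  writeFolds(f, p)
  back <- readFolds(p)
  expect_identical(foldOf(back), foldOf(f))
  unlink(p)
})
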