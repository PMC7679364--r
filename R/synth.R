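# Deterministic synthetic neonate scenes, sequences and cohorts.
#
# Figures are geometric primitives — a (relatively large) elliptical head,
# a rectangular torso, four limb bars — rendered over cluttered backgrounds
# with optional clothing occlusion, illumination gradients and NIR-style
# underexposure. The goal is controllable ground truth for testing, not
# photorealism.

skin_tones <- function() {
  list(light  = c(0.95, 0.80, 0.70),
       medium = c(0.75, 0.55, 0.40),
       dark   = c(0.45, 0.30, 0.22))
}

# body-region geometry in canvas fractions; neonates have a relatively
# large head, the adult preset shrinks it
scene_layout <- function(orientation, preset) {
  head_r <- if (preset == "neonate") c(0.16, 0.13) else c(0.08, 0.065)
  base <- list(
    head = list(center = c(0.25, 0.50), radii = head_r),
    torso = list(rows = c(0.40, 0.72), cols = c(0.36, 0.64)),
    right_arm = list(rows = c(0.42, 0.50), cols = c(0.10, 0.36)),
    left_arm  = list(rows = c(0.42, 0.50), cols = c(0.64, 0.90)),
    right_leg = list(rows = c(0.72, 0.95), cols = c(0.38, 0.46)),
    left_leg  = list(rows = c(0.72, 0.95), cols = c(0.54, 0.62))
  )
  if (orientation == "side") {
    # limbs bunch to one side
    base$right_arm$cols <- c(0.10, 0.36)
    base$left_arm <- list(rows = c(0.52, 0.60), cols = c(0.10, 0.36))
    base$right_leg <- list(rows = c(0.72, 0.95), cols = c(0.30, 0.38))
    base$left_leg <- list(rows = c(0.72, 0.95), cols = c(0.42, 0.50))
  } else if (orientation == "prone") {
    base$head$center <- c(0.28, 0.46)
  }
  base
}

# per-part brightness tints so parts are distinguishable under a single
# skin tone (test scenes need separable ground truth)
part_tints <- c(head = 1.00, torso = 0.92, right_arm = 0.85,
                left_arm = 1.08, right_leg = 0.78, left_leg = 1.15)

#' Generate one synthetic neonate scene
#'
#' Renders the figure described by the spec and its pixel-exact label mask.
#' Occluded torso pixels take a "clothing" color and the background label
#' (only naked skin carries part labels). Deterministic under the spec
#' seed.
#'
#' @param spec a [SceneSpec-class].
#' @param limbShift integer, vertical displacement (rows) of the right arm;
#'   used by [generateSequence()] to inject motion.
#' @return list(image, mask): (H, W, 3) RGB array in [0, 1] (or (H, W, 1)
#'   for NIR) and a [LabelMask-class].
#' @export
#' @examples
#' sc <- generateScene(sceneSpec(canvas = c(64, 64)))
#' table(maskLabels(sc$mask))
generateScene <- function(spec, limbShift = 0L) {
  validObject(spec)
  H <- spec@canvas[1]; W <- spec@canvas[2]
  with_seed(spec@seed, {
    # cluttered background: noise plus random rectangles
    img <- array(stats::runif(H * W * 3, 0.05, 0.30), dim = c(H, W, 3))
    for (i in seq_len(6)) {
      r <- sort(sample.int(H, 2)); c <- sort(sample.int(W, 2))
      col <- stats::runif(3, 0, 0.6)
      for (ch in 1:3) img[r[1]:r[2], c[1]:c[2], ch] <- col[ch]
    }
    lab <- matrix(0L, H, W)
    tone <- skin_tones()[[spec@skinTone]]
    lay <- scene_layout(spec@orientation, spec@layoutPreset)
    rowg <- matrix(seq_len(H), H, W)
    colg <- matrix(seq_len(W), H, W, byrow = TRUE)
    paint <- function(sel, part, index) {
      tint <- part_tints[[part]]
      for (ch in 1:3)
        img[, , ch][sel] <<- clamp(tone[ch] * tint, 0, 1)
      lab[sel] <<- index
    }
    rect_sel <- function(g, shift_rows = 0L) {
      r <- round(g$rows * H) + shift_rows
      c <- round(g$cols * W)
      rowg >= max(1, r[1]) & rowg <= min(H, r[2]) &
        colg >= max(1, c[1]) & colg <= min(W, c[2])
    }
    # paint order: torso and limbs first, head last (head on top)
    paint(rect_sel(lay$torso), "torso", 2L)
    paint(rect_sel(lay$right_arm, as.integer(limbShift)), "right_arm", 3L)
    paint(rect_sel(lay$left_arm), "left_arm", 4L)
    paint(rect_sel(lay$right_leg), "right_leg", 5L)
    paint(rect_sel(lay$left_leg), "left_leg", 6L)
    hc <- lay$head$center * c(H, W)
    hr <- lay$head$radii * c(H, W)
    head_sel <- ((rowg - hc[1]) / hr[1])^2 + ((colg - hc[2]) / hr[2])^2 <= 1
    paint(head_sel, "head", 1L)
    # clothing occlusion over the torso: background label, fabric color
    if (spec@occlusionFraction > 0) {
      tr <- round(lay$torso$rows * H); tc <- round(lay$torso$cols * W)
      cover_rows <- tr[1] + round(spec@occlusionFraction * (tr[2] - tr[1]))
      occ <- rowg >= tr[1] & rowg <= cover_rows &
        colg >= tc[1] & colg <= tc[2] & lab == 2L
      fabric <- stats::runif(3, 0.4, 0.9)
      for (ch in 1:3) img[, , ch][occ] <- fabric[ch]
      lab[occ] <- 0L
    }
    # sensor noise
    img <- img + array(stats::rnorm(H * W * 3, 0, 0.02), dim = dim(img))
    if (spec@illumination == "gradient") {
      g <- matrix(seq(0.55, 1, length.out = W), H, W, byrow = TRUE)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * g
    }
    img <- clamp(img, 0, 1)
    if (spec@modality == "NIR") {
      nir <- img[, , 1] * spec@exposureScale
      img <- array(clamp(nir, 0, 1), dim = c(H, W, 1L))
    } else if (spec@exposureScale != 1) {
      img <- clamp(img * spec@exposureScale, 0, 1)
    }
    list(image = img, mask = labelMask(lab))
  })
}

#' Generate an image sequence with scheduled limb motion
#'
#' Frame 1 is the base scene; each subsequent frame displaces the right arm
#' by the cumulative motion schedule. A zero schedule yields identical
#' frames.
#'
#' @param spec a [SceneSpec-class].
#' @param nFrames number of frames (>= 2).
#' @param motionSchedule numeric vector of per-transition displacements in
#'   rows (length nFrames - 1; recycled if shorter).
#' @return list(frames = list of image arrays, masks = list of
#'   [LabelMask-class]).
#' @export
generateSequence <- function(spec, nFrames, motionSchedule = 0) {
  if (nFrames < 2L) stop("need at least 2 frames")
  sched <- rep_len(motionSchedule, nFrames - 1L)
  shifts <- c(0, cumsum(sched))
  frames <- vector("list", nFrames)
  masks <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    sc <- generateScene(spec, limbShift = round(shifts[i]))
    frames[[i]] <- sc$image
    masks[[i]] <- sc$mask
  }
  list(frames = frames, masks = masks)
}

#' Generate a synthetic recording cohort
#'
#' Draws per-recording metadata (origin, orientation, modality) from the
#' given distributions, renders `framesPerRecording` frames per recording,
#' and optionally writes PNG images, palette PNG masks and the metadata CSV
#' consumed by [assignFolds()]. Metadata is constant within a recording.
#'
#' @param nRecordings number of recordings.
#' @param framesPerRecording frames per recording (scalar or vector).
#' @param originProbs named probabilities over European / North Indian /
#'   South Indian.
#' @param orientationProbs named probabilities over prone / supine / side.
#' @param nirFraction fraction of recordings recorded in NIR.
#' @param canvas scene canvas (divisible by 32).
#' @param seed cohort seed.
#' @param dir output directory for PNGs + metadata.csv; NULL renders
#'   metadata and in-memory scenes only.
#' @param renderFrames if FALSE, only metadata is generated (fold tests).
#' @return list(records = per-frame metadata data.frame with columns
#'   recording_id, subject_origin, orientation, modality, frame_index and
#'   sampling_rate (25 frames/s), samples = list of
#'   `list(image, mask, recordingId)` when rendered, dir).
#' @export
generateCohort <- function(nRecordings, framesPerRecording = 4L,
                           originProbs = c(European = 0.4,
                                           `North Indian` = 0.3,
                                           `South Indian` = 0.3),
                           orientationProbs = c(prone = 0.35, supine = 0.45,
                                                side = 0.2),
                           nirFraction = 0.15,
                           canvas = c(64L, 64L), seed = 1L, dir = NULL,
                           renderFrames = TRUE) {
  if (!is.null(dir) && !renderFrames)
    stop("writing a cohort to disk requires renderFrames = TRUE")
  frames <- rep_len(as.integer(framesPerRecording), nRecordings)
  meta <- with_seed(seed, data.frame(
    recording_id = sprintf("rec%03d", seq_len(nRecordings)),
    subject_origin = sample(names(originProbs), nRecordings, TRUE,
                            originProbs),
    orientation = sample(names(orientationProbs), nRecordings, TRUE,
                         orientationProbs),
    modality = ifelse(stats::runif(nRecordings) < nirFraction, "NIR", "RGB"),
    frames = frames,
    stringsAsFactors = FALSE))
  records <- meta[rep(seq_len(nRecordings), frames),
                  c("recording_id", "subject_origin", "orientation",
                    "modality")]
  records$frame_index <- unlist(lapply(frames, seq_len))
  records$sampling_rate <- 25  # frames/s, the clinical recording rate
  rownames(records) <- NULL
  samples <- NULL
  if (renderFrames) {
    tones <- c("light", "medium", "dark")
    samples <- list()
    for (i in seq_len(nRecordings)) {
      tone <- tones[(i - 1L) %% 3L + 1L]
      for (f in seq_len(frames[i])) {
        sp <- sceneSpec(canvas = canvas, skinTone = tone,
                        orientation = meta$orientation[i],
                        occlusionFraction = 0.3,
                        modality = meta$modality[i],
                        exposureScale = if (meta$modality[i] == "NIR")
                          0.5 else 1,
                        seed = seed * 10000L + i * 100L + f)
        sc <- generateScene(sp)
        samples[[length(samples) + 1L]] <-
          list(image = sc$image, mask = sc$mask,
               recordingId = meta$recording_id[i])
      }
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(records))
    for (j in seq_len(nrow(records))) {
      s <- samples[[j]]
      base <- sprintf("%s_f%02d", records$recording_id[j],
                      records$frame_index[j])
      img <- s$image
      if (dim(img)[3] == 1L) img <- img[, , 1]
      png::writePNG(img, file.path(dir, paste0(base, ".png")))
      writeMask(s$mask, file.path(dir, paste0(base, "_mask.png")))
      paths[j] <- paste0(base, ".png")
    }
    records$frame_path <- paths
    utils::write.csv(records, file.path(dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(records = records, samples = samples, dir = dir)
}
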