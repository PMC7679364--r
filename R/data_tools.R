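# Label-mask I/O, keyframe selection, recording-grouped fold assignment.

palette_rgb <- function() {
  cols <- grDevices::col2rgb(classSchema()$color) / 255
  t(cols)  # 7 x 3, rows in class-index order
}

#' Read / write label masks as palette PNG files
#'
#' Masks are stored as 8-bit RGB PNGs using the published annotation
#' palette (background black, head blue, torso green, right arm red, left
#' arm magenta, right leg cyan, left leg yellow). The round trip is
#' lossless; any color outside the palette is rejected with the offending
#' color and its pixel count.
#'
#' @param mask a [LabelMask-class].
#' @param path PNG file path.
#' @return `writeMask` returns `path` invisibly; `readMask` returns a
#'   [LabelMask-class].
#' @export
writeMask <- function(mask, path) {
  lab <- maskLabels(mask)
  pal <- palette_rgb()
  img <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[lab + 1L, ch], nrow(lab), ncol(lab))
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  lev <- round(img * 255)
  code <- lev[, , 1] * 65536 + lev[, , 2] * 256 + lev[, , 3]
  pal <- round(palette_rgb() * 255)
  pal_code <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  idx <- match(code, pal_code)
  if (anyNA(idx)) {
    bad <- code[is.na(idx)]
    worst <- sort(table(bad), decreasing = TRUE)[1]
    hex <- sprintf("#%06X", as.integer(names(worst)))
    stop("mask '", path, "' contains ", sum(is.na(idx)),
         " pixel(s) outside the class palette; most frequent offending ",
         "color: ", hex, " (", worst, " pixel(s))")
  }
  labelMask(matrix(as.integer(idx - 1L), dim(img)[1], dim(img)[2]))
}

#' Rank keyframes by consecutive-frame differences
#'
#' Scores each transition between consecutive frames by the mean absolute
#' intensity difference over all pixels and channels (larger differences
#' indicate movement) and returns up to `count` frame indices, ordered by
#' score descending, subject to a minimum index gap between selections and
#' an optional minimum score. The frame credited with a transition is the
#' later frame (the one that moved). Ties break toward the earlier index.
#'
#' @param frames list of image arrays with identical dimensions.
#' @param count number of keyframes requested.
#' @param minGap minimum index distance between selected frames (default 1).
#' @param minScore transitions scoring at or below this value are ignored
#'   (default 0: only strictly positive motion qualifies).
#' @return Integer vector of selected frame indices (2..length(frames)),
#'   ordered by score descending. Scores are attached as the "scores"
#'   attribute (one per transition).
#' @export
selectKeyframes <- function(frames, count, minGap = 1L, minScore = 0) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  if (count < 1L) stop("count must be >= 1")
  scores <- vapply(seq_len(length(frames) - 1L), function(t)
    mean(abs(frames[[t + 1L]] - frames[[t]])), numeric(1))
  cand <- which(scores > minScore)
  ord <- cand[order(-scores[cand], cand)]
  sel <- integer()
  for (t in ord) {
    idx <- t + 1L  # frame that moved
    if (all(abs(idx - sel) >= minGap)) sel <- c(sel, idx)
    if (length(sel) >= count) break
  }
  if (length(sel) < count)
    warning("only ", length(sel), " of ", count,
            " requested keyframes available")
  structure(sel, scores = scores)
}

#' Assign recordings to balanced cross-validation folds
#'
#' Greedy balance optimization under the grouping constraint that all
#' frames of a recording share one fold: recordings are sorted by frame
#' count (descending, ties by recording id) and each is assigned to the
#' fold minimizing the balance cost, the sum of squared deviations of
#' per-fold frame counts from their fold means over the balance marginals
#' (per modality: total frames, frames per origin, frames per
#' orientation), so folds come out balanced in frames, origin and
#' orientation for RGB and NIR frames separately. Deterministic.
#'
#' @param records data.frame with columns `recording_id`, `subject_origin`,
#'   `orientation`, `modality`, one row per frame (or with a `frames` count
#'   column and one row per recording).
#' @param k number of folds (default 5).
#' @param seed accepted for interface stability; the optimizer itself is
#'   deterministic.
#' @return A [FoldAssignment-class].
#' @export
assignFolds <- function(records, k = 5L, seed = 1L) {
  req <- c("recording_id", "subject_origin", "orientation", "modality")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (!"frames" %in% names(records)) {
    agg <- stats::aggregate(list(frames = rep(1L, nrow(records))),
                            records[req], FUN = sum)
  } else agg <- records
  agg <- agg[order(-agg$frames, agg$recording_id), ]
  if (anyDuplicated(agg$recording_id))
    stop("recording metadata must be constant within a recording")
  n_rec <- nrow(agg)
  k <- as.integer(k)
  if (k > n_rec)
    stop("k = ", k, " folds exceed the ", n_rec, " available recordings")
  groups <- balance_groups(agg)
  counts <- matrix(0, nrow = k, ncol = ncol(groups),
                   dimnames = list(NULL, colnames(groups)))
  fold_of <- integer(n_rec)
  for (i in seq_len(n_rec)) {
    gi <- which(groups[i, ] > 0)
    costs <- vapply(seq_len(k), function(f) {
      trial <- counts
      trial[f, gi] <- trial[f, gi] + agg$frames[i]
      sum(sweep(trial, 2, colMeans(trial))^2)
    }, numeric(1))
    f <- which.min(costs)  # ties -> lowest fold index
    fold_of[i] <- f
    counts[f, gi] <- counts[f, gi] + agg$frames[i]
  }
  names(fold_of) <- agg$recording_id
  rep_df <- do.call(rbind, lapply(seq_len(k), function(f) {
    rows <- agg[fold_of == f, ]
    data.frame(fold = f, frames = sum(rows$frames),
               recordings = nrow(rows),
               stringsAsFactors = FALSE)
  }))
  rep_df <- cbind(rep_df, as.data.frame.matrix(counts))
  new("FoldAssignment", foldOf = fold_of, k = k, balanceReport = rep_df)
}

# per-recording indicator matrix over the balance marginals: per modality,
# the recording contributes to its total-frames, origin and orientation
# columns
balance_groups <- function(agg) {
  cols <- c(paste0(agg$modality, ":total"),
            paste0(agg$modality, ":", agg$subject_origin),
            paste0(agg$modality, ":or:", agg$orientation))
  lev <- sort(unique(as.character(cols)))
  g <- matrix(0L, nrow(agg), length(lev), dimnames = list(NULL, lev))
  g[cbind(seq_len(nrow(agg)), match(paste0(agg$modality, ":total"), lev))] <- 1L
  g[cbind(seq_len(nrow(agg)),
          match(paste0(agg$modality, ":", agg$subject_origin), lev))] <- 1L
  g[cbind(seq_len(nrow(agg)),
          match(paste0(agg$modality, ":or:", agg$orientation), lev))] <- 1L
  g
}

#' @describeIn assignFolds balance cost of an arbitrary assignment (exposed
#'   for auditing): sum of squared deviations of per-fold frame counts over
#'   the balance marginals.
#' @param foldOf named integer vector recording_id -> fold.
#' @export
foldBalanceCost <- function(records, foldOf, k) {
  if (!"frames" %in% names(records)) {
    req <- c("recording_id", "subject_origin", "orientation", "modality")
    records <- stats::aggregate(list(frames = rep(1L, nrow(records))),
                                records[req], FUN = sum)
  }
  groups <- balance_groups(records)
  counts <- matrix(0, nrow = k, ncol = ncol(groups))
  for (i in seq_len(nrow(records))) {
    f <- foldOf[[records$recording_id[i]]]
    gi <- which(groups[i, ] > 0)
    counts[f, gi] <- counts[f, gi] + records$frames[i]
  }
  sum(sweep(counts, 2, colMeans(counts))^2)
}

#' @describeIn assignFolds fold index per recording id.
#' @param x a [FoldAssignment-class].
#' @export
foldOf <- function(x) x@foldOf

#' Write / read a fold assignment as CSV
#'
#' @param folds a [FoldAssignment-class].
#' @param path CSV path with columns recording_id, fold.
#' @return `writeFolds` returns `path` invisibly; `readFolds` a
#'   [FoldAssignment-class] (without a balance report).
#' @export
writeFolds <- function(folds, path) {
  utils::write.csv(data.frame(recording_id = names(folds@foldOf),
                              fold = folds@foldOf, row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFolds
#' @export
readFolds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fo <- as.integer(df$fold)
  names(fo) <- df$recording_id
  new("FoldAssignment", foldOf = fo, k = max(fo),
      balanceReport = data.frame())
}

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment: ", length(object@foldOf), " recordings in ",
      object@k, " folds\n", sep = "")
  if (nrow(object@balanceReport))
    print(object@balanceReport[, c("fold", "frames", "recordings")],
          row.names = FALSE)
})
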