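# Loss, optimizer schedule, metrics, training harness, cross-validation.

#' Learning rate at a given epoch
#'
#' Constant mode keeps the initial rate (pre-training protocol); step mode
#' halves it every 30 completed epochs (clinical fine-tuning):
#' lr(epoch) = initialLr * 0.5^floor(epoch / 30).
#'
#' @param schedule an [OptimizerSchedule-class].
#' @param epoch completed epochs (0-based), >= 0.
#' @return The learning rate.
#' @export
#' @examples
#' learningRate(optimizerSchedule(decayMode = "step_half_every_30"), 30)
learningRate <- function(schedule, epoch) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  if (schedule@decayMode == "constant") {
    rep(schedule@initialLr, length(epoch))
  } else {
    schedule@initialLr * 0.5^(epoch %/% 30)
  }
}

#' Mean per-pixel cross-entropy
#'
#' Mean over all pixels of -log p(true class). Nonnegative; zero exactly
#' when the true class has probability 1 at every pixel; equal to
#' log(numClasses) under uniform predictions.
#'
#' @param probs a [ProbabilityMap-class] or (H, W, C) probability array.
#' @param truth a [LabelMask-class] or integer matrix with 0-based classes.
#' @return The scalar loss.
#' @export
pixelCrossEntropy <- function(probs, truth) {
  p <- if (is(probs, "ProbabilityMap")) probs@probs else probs
  lab <- if (is(truth, "LabelMask")) maskLabels(truth) else truth
  d <- dim(p)
  if (any(d[1:2] != dim(lab)))
    stop("probability map and truth mask shapes differ")
  if (any(lab < 0L) || any(lab >= d[3]))
    stop("truth labels outside the class alphabet")
  m <- matrix(p, d[1] * d[2], d[3])
  pt <- m[cbind(seq_len(d[1] * d[2]), as.integer(lab) + 1L)]
  mean(-log(pmax(pt, 1e-300)))
}

# confusion matrix (numClasses x numClasses); rows = truth, cols = predicted
confusion_counts <- function(pred, truth, numClasses = 7L) {
  pl <- if (is(pred, "LabelMask")) maskLabels(pred) else pred
  tl <- if (is(truth, "LabelMask")) maskLabels(truth) else truth
  if (any(dim(pl) != dim(tl))) stop("prediction and truth shapes differ")
  idx <- as.integer(tl) * numClasses + as.integer(pl) + 1L
  matrix(tabulate(idx, nbins = numClasses^2), numClasses, numClasses,
         byrow = TRUE)
}

#' Per-class IoU and accuracy
#'
#' Computes, per foreground class c, IoU = TP / (TP + FP + FN) and
#' class-wise pixel accuracy (recall) ACC = TP / (TP + FN). For an image
#' set, confusion counts are accumulated over all images before the ratios
#' are taken (dataset-level metrics). Classes absent from both prediction
#' and truth are reported NA and excluded from the means, which average the
#' six foreground classes.
#'
#' @param pred,truth [LabelMask-class] objects or lists of them (paired).
#' @param numClasses total classes including background (default 7).
#' @return A [MetricsTable-class].
#' @export
#' @examples
#' t <- labelMask(matrix(c(1, 2, 1, 0), 2, 2))
#' evaluateMasks(t, t)
evaluateMasks <- function(pred, truth, numClasses = 7L) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth))
    stop("prediction and truth sets differ in length")
  cm <- matrix(0, numClasses, numClasses)
  for (i in seq_along(pred))
    cm <- cm + confusion_counts(pred[[i]], truth[[i]], numClasses)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  iou <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), NA_real_)
  acc <- ifelse(tp + fn > 0, tp / (tp + fn),
                ifelse(tp + fp + fn > 0, 0, NA_real_))
  # a class predicted but absent from truth: recall undefined on 0 truth
  # pixels; report 0 only when the class appears somewhere (FP), NA never
  acc[tp + fn == 0 & fp > 0] <- 0
  fg <- 2:numClasses  # foreground classes 1..numClasses-1
  per <- data.frame(class = classSchema()$name[seq_len(numClasses)],
                    iou = iou, acc = acc, stringsAsFactors = FALSE)
  new("MetricsTable", perClass = per,
      meanIoU = mean(iou[fg], na.rm = TRUE),
      meanAcc = mean(acc[fg], na.rm = TRUE))
}

#' @describeIn evaluateMasks per-class table (class, iou, acc).
#' @param x a [MetricsTable-class].
#' @export
perClassMetrics <- function(x) x@perClass

#' @describeIn evaluateMasks mean IoU over the six foreground classes.
#' @export
meanIoU <- function(x) x@meanIoU

#' @describeIn evaluateMasks mean accuracy over the six foreground classes.
#' @export
meanAcc <- function(x) x@meanAcc

setMethod("show", "MetricsTable", function(object) {
  per <- object@perClass
  per$iou <- sprintf("%.3f", per$iou)
  per$acc <- sprintf("%.3f", per$acc)
  print(per, row.names = FALSE)
  cat(sprintf("mean IoU %.3f | mean ACC %.3f (foreground classes)\n",
              object@meanIoU, object@meanAcc))
})

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  # m and v must be distinct allocations: the optimizer updates in place
  list(t = 0,
       m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"))
}

adam_step <- function(params, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      # fused in-place update; params/m/v are private to the training run
      nn_adam_update(params[[nm]][[f]], grads[[nm]][[f]],
                     state$m[[nm]][[f]], state$v[[nm]][[f]],
                     lr, b1, b2, eps, c1, c2)
    }
  }
  list(params = params, state = state)
}

# ---- training harness -----------------------------------------------------

# dataset: list of samples, each list(image = (H,W,C) array in [0,1],
# mask = LabelMask, recordingId = optional chr)
check_dataset <- function(dataset, inputSize) {
  if (length(dataset) == 0L) stop("empty dataset")
  for (s in dataset) {
    d <- dim(as_image(s$image))
    if (any(d[1:2] != inputSize))
      stop("sample size ", d[1], " x ", d[2], " does not match the ",
           "configured input size ", inputSize[1], " x ", inputSize[2])
    if (any(d[1:2] != dim(maskLabels(s$mask))))
      stop("image and mask are not congruent")
  }
  invisible(TRUE)
}

batch_tensors <- function(net, samples) {
  x <- prepare_batch(net, lapply(samples, `[[`, "image"))
  labs <- lapply(samples, function(s) maskLabels(s$mask))
  list(x = x, labels = labs)
}

# cross-entropy loss and gradient at the classifier logits
ce_loss_grad <- function(probs, labels) {
  d <- dim(probs)
  hw <- d[1] * d[2]
  g <- probs
  loss <- 0
  for (n in seq_len(d[4])) {
    onehot <- matrix(0, hw, d[3])
    onehot[cbind(seq_len(hw), as.integer(labels[[n]]) + 1L)] <- 1
    p <- matrix(probs[, , , n], hw, d[3])
    loss <- loss - sum(log(pmax(p[onehot == 1], 1e-300))) / hw
    g[, , , n] <- (p - onehot) / (hw * d[4])
  }
  list(loss = loss / d[4], grad = g)
}

#' Train a segmentation network
#'
#' Adam optimization of the per-pixel cross-entropy, fully reproducible
#' under the config seed (shuffling, augmentation, dropout). One epoch is
#' one pass over the training split; the step schedule halves the rate on
#' completed epochs. Supports warm starts from an existing network or
#' checkpoint.
#'
#' @param dataset list of samples, each `list(image =, mask =)` with
#'   congruent (H, W, C) image and [LabelMask-class]; sizes must equal
#'   `config@inputSize`.
#' @param config a [TrainConfig-class].
#' @param net optional [SegmentationNetwork-class] to continue training
#'   (warm start); default builds a fresh model from `config@spec`.
#' @param evalEvery record training metrics every this many epochs
#'   (0 = loss only).
#' @return list(net, log): the trained network and a per-epoch data.frame
#'   with columns epoch, lr, loss and (when evaluated) meanFgIoU.
#' @export
trainModel <- function(dataset, config, net = NULL, evalEvery = 0L) {
  validObject(config)
  check_dataset(dataset, config@inputSize)
  if (is.null(net)) net <- buildModel(config@spec)
  # private copies: the in-place optimizer must not mutate the caller's net
  net@params <- rapply(net@params, function(a) a + 0, how = "replace")
  sch <- config@schedule
  acfg <- profile_config(config@augmentation, config@augmentationProfile)
  augment <- length(acfg@enabledOps) > 0L
  state <- adam_init(net@params)
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                    meanFgIoU = numeric())
  n <- length(dataset)
  bs <- min(config@batchSize, n)
  with_seed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      lr <- learningRate(sch, epoch - 1L)
      ord <- sample.int(n)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        samples <- dataset[take]
        if (augment)
          samples <- lapply(samples, function(s) {
            a <- augmentSample(s$image, s$mask, acfg)
            list(image = a$image, mask = a$mask)
          })
        bt <- batch_tensors(net, samples)
        fw <- run_forward(net, bt$x, training = TRUE)
        net@buffers <- fw$buffers
        probs <- get("softmax", fw$outputs)
        lg <- ce_loss_grad(probs, bt$labels)
        grads <- run_backward(net, bt$x, fw, lg$grad)
        upd <- adam_step(net@params, grads, state, lr,
                         sch@beta1, sch@beta2, sch@epsilon)
        net@params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + lg$loss
        nb <- nb + 1L
      }
      miou <- NA_real_
      if (evalEvery > 0L && (epoch %% evalEvery == 0L ||
                             epoch == config@epochs)) {
        m <- evaluateModel(net, dataset)
        miou <- meanIoU(m)
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   loss = epoch_loss / nb,
                                   meanFgIoU = miou))
    }
  })
  list(net = net, log = log)
}

#' Evaluate a network on a labeled dataset
#'
#' Forward passes in evaluation mode, argmax decoding, and dataset-level
#' IoU/accuracy accumulation.
#'
#' @param net a [SegmentationNetwork-class].
#' @param dataset list of `list(image =, mask =)` samples.
#' @return A [MetricsTable-class].
#' @export
evaluateModel <- function(net, dataset) {
  preds <- lapply(dataset, function(s)
    predictMask(netForward(net, s$image)))
  evaluateMasks(preds, lapply(dataset, `[[`, "mask"))
}

#' Recording-grouped cross-validation
#'
#' For each fold: trains on all other folds and evaluates on the held-out
#' fold, so complete recordings (hence subjects) are left out. A recording
#' mapped to more than one fold, or a sample whose recording is missing
#' from the fold map, is a hard error.
#'
#' @param dataset list of samples, each with a `recordingId` element.
#' @param folds a [FoldAssignment-class], or a named vector
#'   recording_id -> fold.
#' @param config a [TrainConfig-class] used for every per-fold run.
#' @return list(perFold = list of [MetricsTable-class], summary =
#'   data.frame of min/mean/max for meanIoU and meanAcc).
#' @export
crossValidate <- function(dataset, folds, config) {
  fo <- if (is(folds, "FoldAssignment")) folds@foldOf else folds
  ids <- names(fo)
  if (is.null(ids) || anyDuplicated(ids))
    stop("fold map assigns a recording to more than one fold ",
         "(grouping invariant breach)")
  rec <- vapply(dataset, function(s) {
    if (is.null(s$recordingId)) stop("sample lacks a recordingId")
    s$recordingId
  }, character(1))
  if (!all(rec %in% ids))
    stop("recordings missing from the fold map: ",
         paste(unique(rec[!rec %in% ids]), collapse = ", "))
  ks <- sort(unique(fo))
  perFold <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    f <- ks[i]
    test_rec <- ids[fo == f]
    train_set <- dataset[!rec %in% test_rec]
    test_set <- dataset[rec %in% test_rec]
    if (length(train_set) == 0L || length(test_set) == 0L)
      stop("fold ", f, " leaves an empty train or test partition")
    if (any(vapply(train_set, `[[`, character(1), "recordingId") %in%
            test_rec))
      stop("recording appears in both train and test partitions")
    fit <- trainModel(train_set, config)
    perFold[[i]] <- evaluateModel(fit$net, test_set)
  }
  miou <- vapply(perFold, meanIoU, numeric(1))
  macc <- vapply(perFold, meanAcc, numeric(1))
  summary <- data.frame(
    metric = c("meanIoU", "meanAcc"),
    min = c(min(miou), min(macc)),
    mean = c(mean(miou), mean(macc)),
    max = c(max(miou), max(macc)))
  list(perFold = perFold, summary = summary)
}
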