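# shared fixtures and independent oracles, all generated in code

.fixture_env <- new.env()

# a full batchnorm network is expensive to initialize; share one instance
cached_net <- function(variant = "batchnorm") {
  key <- paste0("net_", variant)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- buildModel(modelSpec(variant, randomSeed = 7L))
  .fixture_env[[key]]
}

random_mask <- function(h, w, classes = 0:6) {
  labelMask(matrix(sample(classes, h * w, replace = TRUE), h, w))
}

# brute-force confusion counter: per-pixel loops, no vectorization
bf_confusion <- function(pred, truth, k = 7L) {
  p <- maskLabels(pred); t <- maskLabels(truth)
  cm <- matrix(0, k, k)
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    cm[t[i, j] + 1L, p[i, j] + 1L] <- cm[t[i, j] + 1L, p[i, j] + 1L] + 1
  cm
}

bf_metrics <- function(pred, truth, k = 7L) {
  cm <- bf_confusion(pred, truth, k)
  tp <- diag(cm); fn <- rowSums(cm) - tp; fp <- colSums(cm) - tp
  list(iou = ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), NA_real_),
       acc = ifelse(tp + fn > 0, tp / (tp + fn),
                    ifelse(fp > 0, 0, NA_real_)))
}

# all monotone nondecreasing maps {0..n-1} -> {0..n-1}
monotone_maps <- function(n) {
  out <- list()
  rec <- function(prefix, lo) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in lo:(n - 1L)) rec(c(prefix, v), v)
  }
  rec(integer(), 0L)
  out
}

# histogram-matching objective and feasibility under the package's stated
# rule, recomputed independently on an m-level alphabet: the target
# cumulative at T(k) must reach the tracked level cs(k) - hs(k)/2, and the
# fitted map minimizes the summed exceedance over that level
hm_cost <- function(map, hs, ht) {
  hsn <- hs / sum(hs)
  cs <- cumsum(hsn); ct <- cumsum(ht / sum(ht))
  sum(ct[map + 1L] - (cs - hsn / 2))
}

hm_feasible <- function(map, hs, ht) {
  hsn <- hs / sum(hs)
  cs <- cumsum(hsn); ct <- cumsum(ht / sum(ht))
  all(ct[map + 1L] >= cs - hsn / 2 - 1e-9) && all(diff(map) >= 0)
}

# 8-bit-quantized random RGB image
quantized_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE) / 255, dim = c(h, w, 3))
}

small_scene_set <- function(n, canvas = c(64L, 64L), seed0 = 1L, ...) {
  lapply(seq_len(n), function(i) {
    sc <- generateScene(sceneSpec(canvas = canvas, seed = seed0 + i, ...))
    list(image = sc$image, mask = sc$mask)
  })
}
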