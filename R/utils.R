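# internal helpers

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# coerce an (H, W[, C]) image or an (H, W, C, N) batch to (H, W, C, N)
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  else if (length(d) == 3L) d <- c(d, 1L)
  else if (length(d) != 4L) stop("input must have 2-4 dimensions")
  array(as.numeric(x), dim = d)
}

check_divisible32 <- function(h, w) {
  if (h %% 32L != 0L)
    stop("image height ", h, " is not divisible by 32")
  if (w %% 32L != 0L)
    stop("image width ", w, " is not divisible by 32")
  invisible(TRUE)
}

# round half away from zero at `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
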