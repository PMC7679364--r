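# The network's differentiable kernels are validated against brute-force
# forward computation and central-difference gradients on small tensors.

test_that("convolution forward matches a per-pixel brute-force loop", {
  set.seed(42)
  H <- 7L; W <- 6L; C <- 3L; Co <- 4L; k <- 3L; st <- 2L; pd <- 1L; N <- 2L
  x <- array(rnorm(H * W * C * N), c(H, W, C, N))
  w <- array(rnorm(k * k * C * Co) / 3, c(k, k, C, Co))
  b <- rnorm(Co)
  y <- neoseg:::nn_conv_fw(x, w, b, st, pd)
  Ho <- (H + 2 * pd - k) %/% st + 1L
  Wo <- (W + 2 * pd - k) %/% st + 1L
  ybf <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (oy in 1:Ho) for (ox in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (ky in 1:k) for (kx in 1:k) {
      iy <- (oy - 1L) * st - pd + ky
      ix <- (ox - 1L) * st - pd + kx
      if (iy >= 1 && iy <= H && ix >= 1 && ix <= W)
        acc <- acc + x[iy, ix, ci, n] * w[ky, kx, ci, co]
    }
    ybf[oy, ox, co, n] <- acc
  }
  expect_lt(max(abs(y - ybf)), 1e-5)
})

grad_check <- function(fw, analytic, param, h = 1e-2, n = 8, tol = 5e-4) {
  set.seed(99)
  idx <- sample(length(param), n)
  for (i in idx) {
    p1 <- param; p2 <- param
    p1[i] <- p1[i] + h
    p2[i] <- p2[i] - h
    num <- (fw(p1) - fw(p2)) / (2 * h)
    expect_lt(abs(num - analytic[i]), tol)
  }
}

test_that("convolution gradients agree with finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) / 3, c(3, 3, 2, 3))
  b <- rnorm(3)
  R <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  g <- neoseg:::nn_conv_bw(x, w, R, 1L, 1L, TRUE, TRUE)
  grad_check(function(xx) sum(neoseg:::nn_conv_fw(xx, w, b, 1L, 1L) * R),
             g$gx, x)
  grad_check(function(ww) sum(neoseg:::nn_conv_fw(x, ww, b, 1L, 1L) * R),
             g$gw, w)
  expect_equal(g$gb, apply(R, 3, sum), tolerance = 1e-5)
})

test_that("transposed convolution inverts the conv geometry and its gradients check out", {
  set.seed(2)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  w <- array(rnorm(4 * 4 * 2 * 3) / 4, c(4, 4, 2, 3))
  b <- rnorm(2)
  y <- neoseg:::nn_tconv_fw(x, w, b, 2L, 1L)
  expect_equal(dim(y), c(10L, 8L, 2L, 2L))
  R <- array(rnorm(length(y)), dim(y))
  g <- neoseg:::nn_tconv_bw(x, w, R, 2L, 1L)
  grad_check(function(xx) sum(neoseg:::nn_tconv_fw(xx, w, b, 2L, 1L) * R),
             g$gx, x, h = 1e-3, tol = 1e-6)
  grad_check(function(ww) sum(neoseg:::nn_tconv_fw(x, ww, b, 2L, 1L) * R),
             g$gw, w, h = 1e-3, tol = 1e-6)
})

test_that("batchnorm training statistics and gradients are correct", {
  set.seed(3)
  C <- 3L
  x <- array(rnorm(6 * 5 * C * 2, mean = 2, sd = 3), c(6, 5, C, 2))
  gam <- runif(C, 0.5, 1.5); bet <- rnorm(C)
  r <- neoseg:::nn_bn_fw(x, gam, bet, TRUE, numeric(C), rep(1, C), 0.1, 1e-5)
  for (c in seq_len(C)) {
    xc <- x[, , c, ]
    expect_equal(r$mean[c], mean(xc), tolerance = 1e-12)
    yc <- r$y[, , c, ]
    expect_equal(mean(yc), bet[c], tolerance = 1e-8)
    expect_equal(stats::sd(as.numeric(yc)) * sqrt(59 / 60), gam[c],
                 tolerance = 1e-3)
  }
  R <- array(rnorm(length(x)), dim(x))
  g <- neoseg:::nn_bn_bw(x, R, gam, r$mean, r$invstd)
  grad_check(function(xx)
    sum(neoseg:::nn_bn_fw(xx, gam, bet, TRUE, numeric(C), rep(1, C),
                          0.1, 1e-5)$y * R),
    g$gx, x, h = 1e-4, tol = 1e-5)
})

test_that("maxpool and bilinear resize backward scatter exactly", {
  set.seed(4)
  x <- array(rnorm(8 * 8 * 2 * 1), c(8, 8, 2, 1))
  r <- neoseg:::nn_maxpool_fw(x, 3L, 2L, 1L)
  expect_equal(dim(r$y), c(4L, 4L, 2L, 1L))
  expect_equal(max(r$y), max(x))
  R <- array(rnorm(length(r$y)), dim(r$y))
  g <- neoseg:::nn_maxpool_bw(r$idx, R, dim(x))
  grad_check(function(xx)
    sum(neoseg:::nn_maxpool_fw(xx, 3L, 2L, 1L)$y * R), g, x,
    h = 1e-5, tol = 1e-6)
  y2 <- neoseg:::nn_resize_bilinear_fw(x, 16L, 16L)
  R2 <- array(rnorm(length(y2)), dim(y2))
  g2 <- neoseg:::nn_resize_bilinear_bw(R2, 8L, 8L)
  grad_check(function(xx)
    sum(neoseg:::nn_resize_bilinear_fw(xx, 16L, 16L) * R2), g2, x,
    h = 1e-5, tol = 1e-6)
  # constant image stays constant under resize
  const <- array(3, c(4, 4, 1, 1))
  expect_true(all(neoseg:::nn_resize_bilinear_fw(const, 8L, 8L) == 3))
})

test_that("rotation warp is exact on the identity and fills with zero", {
  set.seed(5)
  x <- array(runif(9 * 9 * 1 * 1), c(9, 9, 1, 1))
  expect_equal(neoseg:::nn_warp_rotate(x, 0, FALSE), x)
  y90 <- neoseg:::nn_warp_rotate(x, 90, TRUE)
  # a 90-degree nearest rotation about the center permutes pixels
  expect_equal(sort(as.numeric(y90)), sort(as.numeric(x)))
  ycorner <- neoseg:::nn_warp_rotate(x, 45, FALSE)
  expect_equal(ycorner[1, 1, 1, 1], 0)  # exposed corner is black
})
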