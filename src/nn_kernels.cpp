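// Low-level tensor kernels for the segmentation network.
//
// Tensor layout: numeric arrays with dim (H, W, C, N), column-major, so the
// row index varies fastest. Convolution weights: dim (kh, kw, Cin, Cout).
// Transposed-convolution weights are stored as the weights of the equivalent
// convolution mapping output -> input, i.e. dim (kh, kw, Cout, Cin).
// All convolutions are realized as im2col + BLAS GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// cols(p, q): p = oy + Ho*ox, q = ky + kh*kx + kh*kw*c
template <typename MT, typename T>
static void im2col(const T* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, MT& cols, size_t row0 = 0) {
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        int q = ky + kh * kx + kh * kw * c;
        auto* col = cols.colptr(q) + row0;
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = ox * stride - pad + kx;
          auto* dst = col + (size_t)Ho * ox;
          if (ix < 0 || ix >= W) {
            for (int oy = 0; oy < Ho; ++oy) dst[oy] = 0;
            continue;
          }
          const T* src = xc + (size_t)ix * H;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = oy * stride - pad + ky;
            dst[oy] = (iy >= 0 && iy < H) ? src[iy] : 0;
          }
        }
      }
    }
  }
}

// scatter-accumulate: inverse of im2col
template <typename MT, typename T>
static void col2im(const MT& cols, T* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int Ho, int Wo,
                   size_t row0 = 0) {
  for (int c = 0; c < C; ++c) {
    T* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        int q = ky + kh * kx + kh * kw * c;
        const auto* col = cols.colptr(q) + row0;
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          T* dst = xc + (size_t)ix * H;
          const auto* src = col + (size_t)Ho * ox;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = oy * stride - pad + ky;
            if (iy >= 0 && iy < H) dst[iy] += src[oy];
          }
        }
      }
    }
  }
}

static arma::fmat to_f(const double* p, size_t nr, size_t nc) {
  arma::fmat m(nr, nc);
  float* q = m.memptr();
  for (size_t i = 0; i < nr * nc; ++i) q[i] = (float)p[i];
  return m;
}

static void from_f(const arma::fmat& m, double* p) {
  const float* q = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) p[i] = (double)q[i];
}

static void add_f(const arma::fmat& m, double* p) {
  const float* q = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) p[i] += (double)q[i];
}

// copy an (nr x nc) double block into rows [row0, row0+nr) of a float mat
static void to_f_rows(const double* p, arma::fmat& m, size_t row0, size_t nr,
                      size_t nc) {
  for (size_t c = 0; c < nc; ++c) {
    float* q = m.colptr(c) + row0;
    const double* src = p + c * nr;
    for (size_t r = 0; r < nr; ++r) q[r] = (float)src[r];
  }
}

static void from_f_rows(const arma::fmat& m, size_t row0, size_t nr,
                        size_t nc, double* p) {
  for (size_t c = 0; c < nc; ++c) {
    const float* q = m.colptr(c) + row0;
    double* dst = p + c * nr;
    for (size_t r = 0; r < nr; ++r) dst[r] = (double)q[r];
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias, int stride, int pad) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv: weight expects %d input channels, got %d", (int)wd[2], C);
  int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat Wm = to_f(w.begin(), (size_t)kh * kw * C, Cout);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  size_t hw = (size_t)Ho * Wo;
  arma::fmat cols((size_t)N * hw, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    if (pointwise)
      to_f_rows(x.begin() + (size_t)n * H * W * C, cols, n * hw, hw, C);
    else
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
             pad, Ho, Wo, cols, n * hw);
  }
  arma::fmat Y = cols * Wm;  // one GEMM for the whole batch
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < Cout; ++c) Y.col(c) += (float)b[c];
  }
  for (int n = 0; n < N; ++n)
    from_f_rows(Y, n * hw, hw, Cout, y.begin() + (size_t)n * hw * Cout);
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, bool has_bias, bool need_gx) {
  IntegerVector xd = dims4(x), wd = dims4(w), yd = dims4(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector gw((size_t)kh * kw * C * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = xd;
  }
  arma::fmat Wm = to_f(w.begin(), (size_t)kh * kw * C, Cout);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  size_t hw = (size_t)Ho * Wo;
  arma::fmat cols((size_t)N * hw, (size_t)kh * kw * C);
  arma::fmat GY((size_t)N * hw, Cout);
  for (int n = 0; n < N; ++n) {
    to_f_rows(gy.begin() + (size_t)n * hw * Cout, GY, n * hw, hw, Cout);
    if (pointwise)
      to_f_rows(x.begin() + (size_t)n * H * W * C, cols, n * hw, hw, C);
    else
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
             pad, Ho, Wo, cols, n * hw);
  }
  if (has_bias) for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(GY.col(c));
  arma::fmat GW = cols.t() * GY;
  from_f(GW, gw.begin());
  if (need_gx) {
    arma::fmat gcols = GY * Wm.t();
    if (pointwise) {
      for (int n = 0; n < N; ++n)
        from_f_rows(gcols, n * hw, hw, C, gx.begin() + (size_t)n * H * W * C);
    } else {
      for (int n = 0; n < N; ++n)
        col2im(gcols, gx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, Ho, Wo, n * hw);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed convolution: weights (kh, kw, Cout, Cin); output
// Ho = (H-1)*stride - 2*pad + kh
// [[Rcpp::export]]
NumericVector nn_tconv_fw(NumericVector x, NumericVector w,
                          Nullable<NumericVector> bias, int stride, int pad) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  if (wd[3] != C) stop("tconv: weight expects %d input channels, got %d", (int)wd[3], C);
  int Ho = (H - 1) * stride - 2 * pad + kh;
  int Wo = (W - 1) * stride - 2 * pad + kw;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cout, C, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat cols = Xm * Wm.t();  // (H*W, kh*kw*Cout)
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    col2im(cols, yn, Ho, Wo, Cout, kh, kw, stride, pad, H, W);
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int c = 0; c < Cout; ++c) {
        double* yc = yn + (size_t)c * Ho * Wo;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += b[c];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_tconv_bw(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad) {
  IntegerVector xd = dims4(x), wd = dims4(w), yd = dims4(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  int Ho = yd[0], Wo = yd[1];
  NumericVector gw((size_t)kh * kw * Cout * C);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cout, C, false, true);
  arma::mat GW(gw.begin(), (size_t)kh * kw * Cout, C, false, true);
  arma::mat colsG((size_t)H * W, (size_t)kh * kw * Cout);
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    im2col(gyn, Ho, Wo, Cout, kh, kw, stride, pad, H, W, colsG);
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat GX(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    GX = colsG * Wm;
    GW += colsG.t() * Xm;
    for (int c = 0; c < Cout; ++c) {
      const double* gyc = gyn + (size_t)c * Ho * Wo;
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += gyc[i];
      gb[c] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based index into x
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int ox = 0; ox < Wo; ++ox) {
        for (int oy = 0; oy < Ho; ++oy) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kx = 0; kx < k; ++kx) {
            int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= H) continue;
              double v = xc[iy + (size_t)ix * H];
              if (v > best) { best = v; besti = iy + ix * H; }
            }
          }
          p = ((size_t)n * C + c) * Ho * Wo + (size_t)ox * Ho + oy;
          y[p] = best;
          idx[p] = (int)(base + besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// batch normalization, channel-wise over (H, W, N)
// [[Rcpp::export]]
List nn_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
              bool training, NumericVector rm, NumericVector rv,
              double momentum, double eps) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mean(C), invstd(C), newRm(clone(rm)), newRv(clone(rv));
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * hw;
        for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu = s / m;
      var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      newRm[c] = (1 - momentum) * rm[c] + momentum * mu;
      newRv[c] = (1 - momentum) * rv[c] + momentum * var * (m > 1 ? m / (m - 1) : 1.0);
    } else {
      mu = rm[c];
      var = rv[c];
    }
    double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu;
    invstd[c] = is;
    double g = gamma[c] * is, b = beta[c] - gamma[c] * is * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      double* yc = y.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) yc[i] = g * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["rm"] = newRm, _["rv"] = newRv);
}

// [[Rcpp::export]]
List nn_bn_bw(NumericVector x, NumericVector gy, NumericVector gamma,
              NumericVector mean, NumericVector invstd) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], is = invstd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      const double* gc = gy.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mu) * is;
        sg += gc[i];
        sgx += gc[i] * xh;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    double k1 = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      const double* gc = gy.begin() + ((size_t)n * C + c) * hw;
      double* gxc = gx.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mu) * is;
        gxc[i] = k1 * (gc[i] - sg / m - xh * sgx / m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector nn_relu_fw(NumericVector x) {
  NumericVector y(clone(x));
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// in place: the incoming gradient buffer is owned by the backward sweep
// and has no other live references once this node is reached
// [[Rcpp::export]]
NumericVector nn_relu_bw(NumericVector y, NumericVector gy) {
  double* g = gy.begin();
  const double* py = y.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) if (py[i] <= 0) g[i] = 0;
  return gy;
}

// bilinear resize with half-pixel centers, edge-clamped
// [[Rcpp::export]]
NumericVector nn_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> y0(Ho), x0(Wo);
  std::vector<double> wy(Ho), wx(Wo);
  for (int oy = 0; oy < Ho; ++oy) {
    double s = (oy + 0.5) * (double)H / Ho - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    y0[oy] = (int)std::floor(s);
    if (y0[oy] > H - 2) y0[oy] = std::max(0, H - 2);
    wy[oy] = s - y0[oy];
    if (H == 1) { y0[oy] = 0; wy[oy] = 0; }
  }
  for (int ox = 0; ox < Wo; ++ox) {
    double s = (ox + 0.5) * (double)W / Wo - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    x0[ox] = (int)std::floor(s);
    if (x0[ox] > W - 2) x0[ox] = std::max(0, W - 2);
    wx[ox] = s - x0[ox];
    if (W == 1) { x0[ox] = 0; wx[ox] = 0; }
  }
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xc = x.begin() + (size_t)nc * H * W;
    double* yc = y.begin() + (size_t)nc * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      int xa = x0[ox], xb = std::min(xa + 1, W - 1);
      double fx = wx[ox];
      const double* ca = xc + (size_t)xa * H;
      const double* cb = xc + (size_t)xb * H;
      double* out = yc + (size_t)ox * Ho;
      for (int oy = 0; oy < Ho; ++oy) {
        int ya = y0[oy], yb = std::min(ya + 1, H - 1);
        double fy = wy[oy];
        out[oy] = (1 - fy) * ((1 - fx) * ca[ya] + fx * cb[ya]) +
                  fy * ((1 - fx) * ca[yb] + fx * cb[yb]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_resize_bilinear_bw(NumericVector gy, int H, int W) {
  IntegerVector yd = dims4(gy);
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int nc = 0; nc < N * C; ++nc) {
    const double* gc = gy.begin() + (size_t)nc * Ho * Wo;
    double* xc = gx.begin() + (size_t)nc * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      double s = (ox + 0.5) * (double)W / Wo - 0.5;
      if (s < 0) s = 0;
      if (s > W - 1) s = W - 1;
      int xa = (int)std::floor(s);
      if (xa > W - 2) xa = std::max(0, W - 2);
      double fx = s - xa;
      if (W == 1) { xa = 0; fx = 0; }
      int xb = std::min(xa + 1, W - 1);
      for (int oy = 0; oy < Ho; ++oy) {
        double t = (oy + 0.5) * (double)H / Ho - 0.5;
        if (t < 0) t = 0;
        if (t > H - 1) t = H - 1;
        int ya = (int)std::floor(t);
        if (ya > H - 2) ya = std::max(0, H - 2);
        double fy = t - ya;
        if (H == 1) { ya = 0; fy = 0; }
        int yb = std::min(ya + 1, H - 1);
        double g = gc[oy + (size_t)ox * Ho];
        xc[ya + (size_t)xa * H] += (1 - fy) * (1 - fx) * g;
        xc[ya + (size_t)xb * H] += (1 - fy) * fx * g;
        xc[yb + (size_t)xa * H] += fy * (1 - fx) * g;
        xc[yb + (size_t)xb * H] += fy * fx * g;
      }
    }
  }
  return gx;
}

// nearest-neighbor resize (label masks, augmentation)
// [[Rcpp::export]]
NumericVector nn_resize_nearest(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> sy(Ho), sx(Wo);
  for (int oy = 0; oy < Ho; ++oy)
    sy[oy] = std::min(H - 1, (int)std::floor((oy + 0.5) * (double)H / Ho));
  for (int ox = 0; ox < Wo; ++ox)
    sx[ox] = std::min(W - 1, (int)std::floor((ox + 0.5) * (double)W / Wo));
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xc = x.begin() + (size_t)nc * H * W;
    double* yc = y.begin() + (size_t)nc * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy)
        yc[oy + (size_t)ox * Ho] = xc[sy[oy] + (size_t)sx[ox] * H];
  }
  return y;
}

// rotate image content by angle_deg (counter-clockwise, pivot = center),
// same output size, zero (black / background) fill
// [[Rcpp::export]]
NumericVector nn_warp_rotate(NumericVector x, double angle_deg, bool nearest) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xc = x.begin() + (size_t)nc * H * W;
    double* yc = y.begin() + (size_t)nc * H * W;
    for (int oc = 0; oc < W; ++oc) {
      for (int orr = 0; orr < H; ++orr) {
        // inverse mapping (rotate output coords by -theta)
        double dr = orr - cr, dc = oc - cc;
        double srow = cr + ct * dr + st * dc;
        double scol = cc - st * dr + ct * dc;
        double v = 0.0;
        if (nearest) {
          int ir = (int)std::lround(srow), ic = (int)std::lround(scol);
          if (ir >= 0 && ir < H && ic >= 0 && ic < W) v = xc[ir + (size_t)ic * H];
        } else {
          int r0 = (int)std::floor(srow), c0 = (int)std::floor(scol);
          double fr = srow - r0, fc = scol - c0;
          for (int a = 0; a <= 1; ++a) {
            int rr = r0 + a;
            if (rr < 0 || rr >= H) continue;
            double wr = a ? fr : 1 - fr;
            for (int b = 0; b <= 1; ++b) {
              int ccx = c0 + b;
              if (ccx < 0 || ccx >= W) continue;
              double wc = b ? fc : 1 - fc;
              v += wr * wc * xc[rr + (size_t)ccx * H];
            }
          }
        }
        yc[orr + (size_t)oc * H] = v;
      }
    }
  }
  return y;
}

// in-place variant used by the forward executor: the pre-activation buffer
// is never consumed by any other node or by the backward pass
// [[Rcpp::export]]
NumericVector nn_relu_fw_inplace(NumericVector x) {
  double* p = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) if (p[i] < 0) p[i] = 0;
  return x;
}

// fused in-place Adam update (bias-corrected); mutates p, m, v
// [[Rcpp::export]]
void nn_adam_update(NumericVector p, NumericVector g, NumericVector m,
                    NumericVector v, double lr, double b1, double b2,
                    double eps, double c1, double c2) {
  double* pp = p.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}
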