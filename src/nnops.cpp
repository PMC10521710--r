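// Low-level image / tensor kernels.
//
// Tensor layout follows R column-major arrays:
//   feature maps  x[h, w, c, n]   (height fastest)
//   conv kernels  w[kh, kw, cin, cout]
// Convolutions use zero "same" padding; pooling assumes even spatial dims.
// GEMM-heavy paths run in single precision (arma::fmat); callers that need
// higher accuracy (unit tests) compare against double-precision R oracles
// with tolerances that account for this.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int K, int pad, int stride) {
  return (H + 2 * pad - K) / stride + 1;
}

static IntegerVector need_dim(const NumericVector& x, int nd,
                              const char* what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d) || Rf_length(d) != nd)
    stop("%s must be a %d-d array", what, nd);
  return IntegerVector(d);
}

// Build the im2col matrix: rows indexed by (ho, wo, n), cols by (kh, kw, cin).
static arma::fmat im2col(const double* x, int H, int W, int C, int N,
                         int K, int pad, int stride, int Ho, int Wo) {
  arma::fmat Xc(static_cast<size_t>(Ho) * Wo * N, static_cast<size_t>(K) * K * C,
                arma::fill::zeros);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int cin = 0; cin < C; ++cin) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const size_t col = kh + K * (kw + K * (size_t)cin);
        float* xc = Xc.colptr(col);
        // valid output range: 0 <= ho*stride + kh - pad < H
        int ho_lo = std::max(0, (pad - kh + stride - 1) / stride);
        int ho_hi = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + HW * (cin + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xs + (size_t)H * wi + (size_t)kh - pad;
            float* dst = xc + Ho * ((size_t)wo + (size_t)Wo * n);
            if (stride == 1) {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                dst[ho] = static_cast<float>(xcol[ho]);
            } else {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                dst[ho] = static_cast<float>(xcol[(size_t)ho * stride]);
            }
          }
        }
      }
    }
  }
  return Xc;
}

// 1x1 convolution: no im2col needed, columns are contiguous per (cin, n)
static arma::fmat im2col_1x1(const double* x, int H, int W, int C, int N) {
  arma::fmat Xc(static_cast<size_t>(H) * W * N, C);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int cin = 0; cin < C; ++cin) {
    float* xc = Xc.colptr(cin);
    for (int n = 0; n < N; ++n) {
      const double* xs = x + HW * (cin + (size_t)C * n);
      float* dst = xc + HW * n;
      for (size_t i = 0; i < HW; ++i) dst[i] = static_cast<float>(xs[i]);
    }
  }
  return Xc;
}

static arma::fmat build_xc(const double* x, int H, int W, int C, int N, int K,
                           int pad, int stride, int Ho, int Wo) {
  if (K == 1 && stride == 1) return im2col_1x1(x, H, W, C, N);
  return im2col(x, H, W, C, N, K, pad, stride, Ho, Wo);
}

// [[Rcpp::export(name = "cpp_conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride) {
  IntegerVector xd = need_dim(x, 4, "x"), wd = need_dim(w, 4, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  if (b.size() != Cout) stop("conv2d: bias length mismatch");
  const int pad = (K - 1) / 2;
  const int Ho = out_dim(H, K, pad, stride), Wo = out_dim(W, K, pad, stride);

  arma::fmat Xc = build_xc(REAL(x), H, W, C, N, K, pad, stride, Ho, Wo);
  arma::fmat Wm(static_cast<size_t>(K) * K * Cin, Cout);
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < (size_t)K * K * Cin; ++i)
      Wm(i, j) = static_cast<float>(w[i + (size_t)K * K * Cin * j]);
  arma::fmat Y = Xc * Wm;

  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int wo = 0; wo < Wo; ++wo) {
        const size_t row0 = Ho * ((size_t)wo + (size_t)Wo * n);
        size_t oi = (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Cout * n));
        for (int ho = 0; ho < Ho; ++ho)
          o[oi + ho] = Y(row0 + ho, co) + bc;
      }
    }
  return out;
}

static List conv2d_bwd_core(const arma::fmat& Xc, IntegerVector xd,
                            NumericVector w, NumericVector gy, int stride) {
  IntegerVector wd = need_dim(w, 4, "w"), gd = need_dim(gy, 4, "gy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  const int pad = (K - 1) / 2;
  const int Ho = gd[0], Wo = gd[1];
  arma::fmat Gy(static_cast<size_t>(Ho) * Wo * N, Cout);
  const double* g = REAL(gy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo) {
        size_t gi = (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Cout * n));
        size_t row0 = Ho * ((size_t)wo + (size_t)Wo * n);
        for (int ho = 0; ho < Ho; ++ho)
          Gy(row0 + ho, co) = static_cast<float>(g[gi + ho]);
      }

  arma::fmat Wm(static_cast<size_t>(K) * K * Cin, Cout);
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < (size_t)K * K * Cin; ++i)
      Wm(i, j) = static_cast<float>(w[i + (size_t)K * K * Cin * j]);

  arma::fmat Gw = Xc.t() * Gy;                  // (K*K*Cin) x Cout
  arma::fmat Gc = Gy * Wm.t();                  // rows x (K*K*Cin)

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < (size_t)K * K * Cin; ++i)
      gw[i + (size_t)K * K * Cin * j] = Gw(i, j);

  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(Gy.col(co));

  // col2im scatter-add
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xd;
  double* gxp = REAL(gx);
  const size_t HW = static_cast<size_t>(H) * W;
  if (K == 1 && stride == 1) {
    for (int cin = 0; cin < C; ++cin) {
      const float* gc = Gc.colptr(cin);
      for (int n = 0; n < N; ++n) {
        double* gs = gxp + HW * (cin + (size_t)C * n);
        const float* src = gc + HW * n;
        for (size_t i = 0; i < HW; ++i) gs[i] += src[i];
      }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  for (int cin = 0; cin < C; ++cin)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const size_t col = kh + K * (kw + K * (size_t)cin);
        const float* gc = Gc.colptr(col);
        int ho_lo = std::max(0, (pad - kh + stride - 1) / stride);
        int ho_hi = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
        for (int n = 0; n < N; ++n) {
          double* gs = gxp + HW * (cin + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            double* gcolp = gs + (size_t)H * wi + (size_t)kh - pad;
            const float* src = gc + Ho * ((size_t)wo + (size_t)Wo * n);
            if (stride == 1) {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                gcolp[ho] += src[ho];
            } else {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                gcolp[(size_t)ho * stride] += src[ho];
            }
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = "cpp_conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride) {
  IntegerVector xd = need_dim(x, 4, "x"), wd = need_dim(w, 4, "w"),
      gd = need_dim(gy, 4, "gy");
  const int K = wd[0], pad = (K - 1) / 2;
  arma::fmat Xc = build_xc(REAL(x), xd[0], xd[1], xd[2], xd[3], K, pad,
                           stride, gd[0], gd[1]);
  return conv2d_bwd_core(Xc, xd, w, gy, stride);
}

// Forward pass that also hands back the im2col workspace so the backward
// pass does not need to rebuild it (used by the training tape).
// [[Rcpp::export(name = "cpp_conv2d_fwd_cache")]]
List conv2d_fwd_cache(NumericVector x, NumericVector w, NumericVector b,
                      int stride) {
  IntegerVector xd = need_dim(x, 4, "x"), wd = need_dim(w, 4, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  const int pad = (K - 1) / 2;
  const int Ho = out_dim(H, K, pad, stride), Wo = out_dim(W, K, pad, stride);
  arma::fmat* Xc = new arma::fmat(
      build_xc(REAL(x), H, W, C, N, K, pad, stride, Ho, Wo));
  arma::fmat Wm(static_cast<size_t>(K) * K * Cin, Cout);
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < (size_t)K * K * Cin; ++i)
      Wm(i, j) = static_cast<float>(w[i + (size_t)K * K * Cin * j]);
  arma::fmat Y = (*Xc) * Wm;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int wo = 0; wo < Wo; ++wo) {
        const size_t row0 = Ho * ((size_t)wo + (size_t)Wo * n);
        size_t oi = (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Cout * n));
        for (int ho = 0; ho < Ho; ++ho)
          o[oi + ho] = Y(row0 + ho, co) + bc;
      }
    }
  XPtr<arma::fmat> ptr(Xc, true);
  return List::create(_["y"] = out, _["cache"] = ptr);
}

// [[Rcpp::export(name = "cpp_conv2d_bwd_cached")]]
List conv2d_bwd_cached(SEXP cache, IntegerVector xd, NumericVector w,
                       NumericVector gy, int stride) {
  XPtr<arma::fmat> ptr(cache);
  return conv2d_bwd_core(*ptr, xd, w, gy, stride);
}

// Input-gradient-only backward pass (frozen weights, e.g. the discriminator
// during a generator update): skips the weight-gradient GEMM entirely.
// [[Rcpp::export(name = "cpp_conv2d_bwd_x")]]
NumericVector conv2d_bwd_x(IntegerVector xd, NumericVector w,
                           NumericVector gy, int stride) {
  IntegerVector wd = need_dim(w, 4, "w"), gd = need_dim(gy, 4, "gy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  const int pad = (K - 1) / 2;
  const int Ho = gd[0], Wo = gd[1];
  arma::fmat Gy(static_cast<size_t>(Ho) * Wo * N, Cout);
  const double* g = REAL(gy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo) {
        size_t gi = (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Cout * n));
        size_t row0 = Ho * ((size_t)wo + (size_t)Wo * n);
        for (int ho = 0; ho < Ho; ++ho)
          Gy(row0 + ho, co) = static_cast<float>(g[gi + ho]);
      }
  arma::fmat Wm(static_cast<size_t>(K) * K * Cin, Cout);
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < (size_t)K * K * Cin; ++i)
      Wm(i, j) = static_cast<float>(w[i + (size_t)K * K * Cin * j]);
  arma::fmat Gc = Gy * Wm.t();
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xd;
  double* gxp = REAL(gx);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int cin = 0; cin < C; ++cin)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const size_t col = kh + K * (kw + K * (size_t)cin);
        const float* gc = Gc.colptr(col);
        int ho_lo = std::max(0, (pad - kh + stride - 1) / stride);
        int ho_hi = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
        for (int n = 0; n < N; ++n) {
          double* gs = gxp + HW * (cin + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            double* gcolp = gs + (size_t)H * wi + (size_t)kh - pad;
            const float* src = gc + Ho * ((size_t)wo + (size_t)Wo * n);
            if (stride == 1) {
              for (int ho = ho_lo; ho < ho_hi; ++ho) gcolp[ho] += src[ho];
            } else {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                gcolp[(size_t)ho * stride] += src[ho];
            }
          }
        }
      }
  return gx;
}

// Leaky ReLU forward / backward (backward recovers the mask from y).
// [[Rcpp::export(name = "cpp_lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export(name = "cpp_lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector y, NumericVector gy, double slope) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* yp = REAL(y); const double* gp = REAL(gy);
  double* xp = REAL(gx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i)
    xp[i] = yp[i] > 0 ? gp[i] : slope * gp[i];
  return gx;
}

// [[Rcpp::export(name = "cpp_maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      size_t off = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 0;
          double bv = -1e300;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              double v = xs[(2 * ho + dh) + (size_t)H * (2 * wo + dw)];
              if (v > bv) { bv = v; best = dh + 2 * dw; }
            }
          size_t oi = off + ho + (size_t)Ho * wo;
          yp[oi] = bv;
          ip[oi] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  const int* ip = INTEGER(idx);
  double* xp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      size_t off = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t oi = off + ho + (size_t)Ho * wo;
          int dh = ip[oi] % 2, dw = ip[oi] / 2;
          xs[(2 * ho + dh) + (size_t)H * (2 * wo + dw)] += gp[oi];
        }
    }
  return gx;
}

// Bilinear x2 upsampling, half-pixel convention (output o samples input at
// o/2 - 0.25, edges clamped) -- matches the usual align_corners = FALSE rule.
static void up2_weights(int o, int H, int& i0, int& i1, double& t) {
  double src = 0.5 * o - 0.25;
  double f = std::floor(src);
  t = src - f;
  i0 = std::max(0, std::min(H - 1, (int)f));
  i1 = std::max(0, std::min(H - 1, (int)f + 1));
}

// [[Rcpp::export(name = "cpp_upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> tr(Ho), tc(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, r0[o], r1[o], tr[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, c0[o], c1[o], tc[o]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      double* ys = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double a = xs[r0[ho] + (size_t)H * c0[wo]];
          double b = xs[r1[ho] + (size_t)H * c0[wo]];
          double cc = xs[r0[ho] + (size_t)H * c1[wo]];
          double d = xs[r1[ho] + (size_t)H * c1[wo]];
          ys[ho + (size_t)Ho * wo] =
            (1 - tr[ho]) * (1 - tc[wo]) * a + tr[ho] * (1 - tc[wo]) * b +
            (1 - tr[ho]) * tc[wo] * cc + tr[ho] * tc[wo] * d;
        }
    }
  return y;
}

// [[Rcpp::export(name = "cpp_upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> tr(Ho), tc(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, r0[o], r1[o], tr[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, c0[o], c1[o], tc[o]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gs = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gs[ho + (size_t)Ho * wo];
          xs[r0[ho] + (size_t)H * c0[wo]] += (1 - tr[ho]) * (1 - tc[wo]) * g;
          xs[r1[ho] + (size_t)H * c0[wo]] += tr[ho] * (1 - tc[wo]) * g;
          xs[r0[ho] + (size_t)H * c1[wo]] += (1 - tr[ho]) * tc[wo] * g;
          xs[r1[ho] + (size_t)H * c1[wo]] += tr[ho] * tc[wo] * g;
        }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Resampling / warping

static inline double bilin_at(const double* im, int H, int W, double r,
                              double c, bool constant_fill, double fill) {
  if (constant_fill && (r < 0 || r > H - 1 || c < 0 || c > W - 1)) return fill;
  r = std::max(0.0, std::min((double)H - 1, r));
  c = std::max(0.0, std::min((double)W - 1, c));
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(H - 1, r0 + 1), c1 = std::min(W - 1, c0 + 1);
  double tr = r - r0, tc = c - c0;
  double a = im[r0 + (size_t)H * c0], b = im[r1 + (size_t)H * c0];
  double cc = im[r0 + (size_t)H * c1], d = im[r1 + (size_t)H * c1];
  return (1 - tr) * (1 - tc) * a + tr * (1 - tc) * b + (1 - tr) * tc * cc +
         tr * tc * d;
}

// Pull-back warp: out(r, c) = img(r + dr(r,c), c + dc(r,c)).
// fill_mode 0 = replicate edge, 1 = constant fill value.
// [[Rcpp::export(name = "cpp_warp_bilinear")]]
NumericVector warp_bilinear(NumericVector img, NumericMatrix dr,
                            NumericMatrix dc, int fill_mode, double fill) {
  IntegerVector xd = img.attr("dim");
  const int H = xd[0], W = xd[1];
  const int C = xd.size() >= 3 ? xd[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double* ip = REAL(img);
  double* op = REAL(out);
  const bool cf = fill_mode == 1;
  for (int ch = 0; ch < C; ++ch) {
    const double* im = ip + (size_t)H * W * ch;
    double* om = op + (size_t)H * W * ch;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        om[r + (size_t)H * c] =
          bilin_at(im, H, W, r + dr(r, c), c + dc(r, c), cf, fill);
  }
  return out;
}

// Nearest-neighbour variant (used for label images).
// [[Rcpp::export(name = "cpp_warp_nearest")]]
NumericVector warp_nearest(NumericVector img, NumericMatrix dr,
                           NumericMatrix dc, double fill) {
  IntegerVector xd = img.attr("dim");
  const int H = xd[0], W = xd[1];
  const int C = xd.size() >= 3 ? xd[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double* ip = REAL(img);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* im = ip + (size_t)H * W * ch;
    double* om = op + (size_t)H * W * ch;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        int sr = (int)std::lround(r + dr(r, c));
        int sc = (int)std::lround(c + dc(r, c));
        om[r + (size_t)H * c] =
          (sr < 0 || sr >= H || sc < 0 || sc >= W) ? fill
                                                   : im[sr + (size_t)H * sc];
      }
  }
  return out;
}

// General bilinear resize (matrix in, matrix out), half-pixel convention.
// [[Rcpp::export(name = "cpp_resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix img, int Ho, int Wo) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Ho, Wo);
  const double sr = (double)H / Ho, sc = (double)W / Wo;
  for (int c = 0; c < Wo; ++c)
    for (int r = 0; r < Ho; ++r)
      out(r, c) = bilin_at(REAL(img), H, W, (r + 0.5) * sr - 0.5,
                           (c + 0.5) * sc - 0.5, false, 0.0);
  return out;
}

// Box downsample by an integer factor (pyramid construction).
// [[Rcpp::export(name = "cpp_box_downsample")]]
NumericMatrix box_downsample(NumericMatrix img, int f) {
  const int H = img.nrow() / f, W = img.ncol() / f;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int dc = 0; dc < f; ++dc)
        for (int dr = 0; dr < f; ++dr) s += img(r * f + dr, c * f + dc);
      out(r, c) = s / (f * f);
    }
  return out;
}

// Separable Gaussian blur with replicated edges.
// [[Rcpp::export(name = "cpp_gauss_blur")]]
NumericMatrix gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = std::max(0, std::min(H - 1, r + i));
        a += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = a;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = std::max(0, std::min(W - 1, c + i));
        a += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = a;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Block matching (normalized cross-correlation) for elastic registration.
//
// For each block of `fixed` (top-left on a regular grid), searches integer
// shifts within +/- radius for the highest NCC against `moving`, then refines
// to sub-pixel precision with a 1-D parabola fit in each axis.
// Returns one row per block: [center_r, center_c, dr, dc, ncc, valid]
// (0-based centers; dr/dc is the displacement at which moving matches fixed).
// [[Rcpp::export(name = "cpp_block_ncc")]]
NumericMatrix block_ncc(NumericMatrix fixed, NumericMatrix moving, int block,
                        int step, int radius) {
  const int H = fixed.nrow(), W = fixed.ncol();
  std::vector<double> rows;
  auto ncc_at = [&](int r0, int c0, int dr, int dc, bool& ok) -> double {
    // correlate fixed[r0..r0+block) with moving shifted by (dr, dc)
    if (r0 + dr < 0 || c0 + dc < 0 || r0 + dr + block > H ||
        c0 + dc + block > W) { ok = false; return -2.0; }
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    const int n = block * block;
    for (int c = 0; c < block; ++c)
      for (int r = 0; r < block; ++r) {
        double a = fixed(r0 + r, c0 + c);
        double b = moving(r0 + dr + r, c0 + dc + c);
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
    double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
    if (va < 1e-8 || vb < 1e-8) { ok = false; return -2.0; }
    ok = true;
    return (sab - sa * sb / n) / std::sqrt(va * vb);
  };
  for (int c0 = 0; c0 + block <= W; c0 += step)
    for (int r0 = 0; r0 + block <= H; r0 += step) {
      int bdr = 0, bdc = 0;
      double best = -2.0;
      bool any = false;
      for (int dc = -radius; dc <= radius; ++dc)
        for (int dr = -radius; dr <= radius; ++dr) {
          bool ok;
          double v = ncc_at(r0, c0, dr, dc, ok);
          if (ok && v > best) { best = v; bdr = dr; bdc = dc; any = true; }
        }
      double fdr = bdr, fdc = bdc, valid = any ? 1.0 : 0.0;
      if (any) {
        // parabola refinement; the offset is clamped to half a pixel so a
        // flat curvature cannot throw the estimate
        bool ok1, ok2;
        double vm = ncc_at(r0, c0, bdr - 1, bdc, ok1);
        double vp = ncc_at(r0, c0, bdr + 1, bdc, ok2);
        if (ok1 && ok2) {
          double den = vm - 2 * best + vp;
          if (den < -1e-9) {
            double off = 0.5 * (vm - vp) / den;
            fdr = bdr + std::max(-0.5, std::min(0.5, off));
          }
        }
        vm = ncc_at(r0, c0, bdr, bdc - 1, ok1);
        vp = ncc_at(r0, c0, bdr, bdc + 1, ok2);
        if (ok1 && ok2) {
          double den = vm - 2 * best + vp;
          if (den < -1e-9) {
            double off = 0.5 * (vm - vp) / den;
            fdc = bdc + std::max(-0.5, std::min(0.5, off));
          }
        }
      }
      double cr = r0 + (block - 1) / 2.0, cc = c0 + (block - 1) / 2.0;
      rows.insert(rows.end(), {cr, cc, fdr, fdc, best, valid});
    }
  const int nb = rows.size() / 6;
  NumericMatrix out(nb, 6);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = rows[6 * i + j];
  colnames(out) = CharacterVector::create("center_r", "center_c", "dr", "dc",
                                          "ncc", "valid");
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology and connected components

// [[Rcpp::export(name = "cpp_label_components")]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int n8r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int n8c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      stack.push_back({r, c});
      while (!stack.empty()) {
        auto [cr, cc] = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = cr + n8r[k], c2 = cc + n8c[k];
          if (rr < 0 || rr >= H || c2 < 0 || c2 >= W) continue;
          if (mask(rr, c2) && !lab(rr, c2)) {
            lab(rr, c2) = next;
            stack.push_back({rr, c2});
          }
        }
      }
    }
  return lab;
}

// One fused AdamW update: returns updated parameter and moment estimates.
// [[Rcpp::export(name = "cpp_adamw_update")]]
List adamw_update(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double lr, double wd, double b1,
                  double b2, double bc1, double bc2, double eps) {
  const R_xlen_t n = p.size();
  NumericVector po(n), mo(n), vo(n);
  po.attr("dim") = p.attr("dim");
  const double* pp = REAL(p); const double* gp = REAL(g);
  const double* mp = REAL(m); const double* vp = REAL(v);
  double* pop = REAL(po); double* mop = REAL(mo); double* vop = REAL(vo);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = b1 * mp[i] + (1 - b1) * gp[i];
    const double vi = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    mop[i] = mi; vop[i] = vi;
    pop[i] = pp[i] - lr * ((mi / bc1) / (std::sqrt(vi / bc2) + eps) +
                           wd * pp[i]);
  }
  return List::create(_["p"] = po, _["m"] = mo, _["v"] = vo);
}
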