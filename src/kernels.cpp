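// Layer primitives for the unrolled PDE network.
//
// Tensors are R numeric arrays with dim (H, W, C, B), column-major, so the
// linear index of (i, j, c, b) is i + H*(j + W*(c + C*b)) (0-based).
// Convolution weights are (K*K*Cin) x Cout matrices whose row index
// enumerates (ki, kj, ci) with ki fastest; this matches the im2col column
// layout below. Convolutions are "same" with zero padding; K must be odd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void check_dim4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, B) tensor");
}

static NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Convolutions default to single precision (the conventional deep-learning
// precision): im2col gathers into float, the GEMM uses sgemm, results are
// returned as R doubles. A double-precision path (single = false) backs the
// finite-difference gradient checks in the test suite, which need exact
// piecewise linearity.

// Gather the K x K neighbourhood of every pixel of sample b into col
// (H*W rows, K*K*Cin columns). Out-of-image taps are zero.
template <typename T>
static void im2col(const double* x, int H, int W, int Cin, int b,
                   int K, arma::Mat<T>& col) {
  const int pad = K / 2;
  const size_t plane = (size_t)H * W;
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + plane * (ci + (size_t)Cin * b);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int c = ki + K * (kj + K * ci);
        T* dst = col.colptr(c);
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, pad - ki);
          const int i1 = std::min(H, H + pad - ki);
          const double* src = xc + (size_t)H * jj + (i0 + ki - pad);
          T* d = dst + (size_t)H * j + i0;
          for (int i = i0; i < i1; ++i) *d++ = (T)*src++;
        }
      }
    }
  }
}

// Scatter-add of im2col's adjoint: G has the same layout as col.
template <typename T>
static void col2im(const arma::Mat<T>& G, int H, int W, int Cin, int b,
                   int K, double* dx) {
  const int pad = K / 2;
  const size_t plane = (size_t)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + plane * (ci + (size_t)Cin * b);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int c = ki + K * (kj + K * ci);
        const T* src0 = G.colptr(c);
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, pad - ki);
          const int i1 = std::min(H, H + pad - ki);
          const T* src = src0 + (size_t)H * j + i0;
          double* dst = xc + (size_t)H * jj + (i0 + ki - pad);
          for (int i = i0; i < i1; ++i) *dst++ += *src++;
        }
      }
    }
  }
}

template <typename T>
static void conv_fwd_impl(const NumericVector& x, const NumericMatrix& w,
                          const NumericVector& bias, int K,
                          int H, int W, int Cin, int B, int Cout,
                          NumericVector& y) {
  arma::Mat<T> wm(w.nrow(), Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < w.nrow(); ++r) wm(r, co) = (T)w(r, co);
  arma::Mat<T> col((size_t)H * W, (size_t)K * K * Cin);
  arma::Mat<T> ym((size_t)H * W, Cout);
  for (int b = 0; b < B; ++b) {
    im2col<T>(x.begin(), H, W, Cin, b, K, col);
    ym = col * wm;
    double* yp = y.begin() + (size_t)H * W * Cout * b;
    for (int co = 0; co < Cout; ++co) {
      const T* src = ym.colptr(co);
      const double bs = bias[co];
      for (size_t k = 0; k < (size_t)H * W; ++k)
        yp[(size_t)H * W * co + k] = (double)src[k] + bs;
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                         int K, bool single = true) {
  check_dim4(x);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], B = d[3];
  const int Cout = w.ncol();
  if (w.nrow() != K * K * Cin) stop("weight rows != K*K*Cin");
  NumericVector y = num4(H, W, Cout, B);
  if (single) conv_fwd_impl<float>(x, w, bias, K, H, W, Cin, B, Cout, y);
  else conv_fwd_impl<double>(x, w, bias, K, H, W, Cin, B, Cout, y);
  return y;
}

template <typename T>
static void conv_bwd_impl(const NumericVector& x, const NumericMatrix& w,
                          const NumericVector& dy, int K,
                          int H, int W, int Cin, int B, int Cout,
                          NumericVector& dx, NumericMatrix& dw,
                          NumericVector& db) {
  arma::Mat<T> wm(w.nrow(), Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < w.nrow(); ++r) wm(r, co) = (T)w(r, co);
  arma::Mat<T> dwm(w.nrow(), Cout, arma::fill::zeros);
  arma::Mat<T> col((size_t)H * W, (size_t)K * K * Cin);
  arma::Mat<T> dym((size_t)H * W, Cout);
  for (int b = 0; b < B; ++b) {
    const double* dyp = dy.begin() + (size_t)H * W * Cout * b;
    for (int co = 0; co < Cout; ++co) {
      T* dst = dym.colptr(co);
      double acc = 0;
      for (size_t k = 0; k < (size_t)H * W; ++k) {
        const double v = dyp[(size_t)H * W * co + k];
        dst[k] = (T)v; acc += v;
      }
      db[co] += acc;
    }
    im2col<T>(x.begin(), H, W, Cin, b, K, col);
    dwm += col.t() * dym;
    arma::Mat<T> G = dym * wm.t();
    col2im<T>(G, H, W, Cin, b, K, dx.begin());
  }
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < w.nrow(); ++r) dw(r, co) = (double)dwm(r, co);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy, int K,
                bool single = true) {
  check_dim4(x); check_dim4(dy);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], B = d[3];
  const int Cout = w.ncol();
  NumericVector dx = num4(H, W, Cin, B);
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  if (single) conv_bwd_impl<float>(x, w, dy, K, H, W, Cin, B, Cout, dx, dw, db);
  else conv_bwd_impl<double>(x, w, dy, K, H, W, Cin, B, Cout, dx, dw, db);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  check_dim4(x);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, B);
  IntegerVector idx = int4(Ho, Wo, C, B);  // 0-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin(); int* ip = idx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * b);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t best = off + (size_t)H * (2 * j) + 2 * i;
          double bv = xp[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          *yp++ = bv; *ip++ = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector xdim) {
  NumericVector dx = num4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const double* dyp = dy.begin(); const int* ip = idx.begin();
  double* dxp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) dxp[ip[k]] += dyp[k];
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  check_dim4(x);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  NumericVector y = num4(2 * H, 2 * W, C, B);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = *xp++;
          const size_t o = (size_t)4 * H * W * (c + (size_t)C * b) +
                           (size_t)2 * H * (2 * j) + 2 * i;
          yp[o] = v; yp[o + 1] = v;
          yp[o + 2 * H] = v; yp[o + 2 * H + 1] = v;
        }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  check_dim4(dy);
  IntegerVector d = dy.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], B = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx = num4(H, W, C, B);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const size_t o = (size_t)H2 * W2 * (c + (size_t)C * b) +
                           (size_t)H2 * (2 * j) + 2 * i;
          *dxp++ = dyp[o] + dyp[o + 1] + dyp[o + H2] + dyp[o + H2 + 1];
        }
  return dx;
}

// Batch normalization over (H, W, B) per channel, training mode.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  check_dim4(x);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y = num4(H, W, C, B), mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + plane * (c + (size_t)C * b);
      for (size_t k = 0; k < plane; ++k) { s += xp[k]; s2 += xp[k] * xp[k]; }
    }
    const double n = (double)plane * B;
    const double m = s / n, v = s2 / n - m * m;
    mu[c] = m; var[c] = v > 0 ? v : 0;
    const double sc = gamma[c] / std::sqrt(var[c] + eps), sh = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + plane * (c + (size_t)C * b);
      double* yp = y.begin() + plane * (c + (size_t)C * b);
      for (size_t k = 0; k < plane; ++k) yp[k] = sc * (xp[k] - m) + sh;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
            NumericVector mu, NumericVector var, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector dx = num4(H, W, C, B), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c];
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + plane * (c + (size_t)C * b);
      const double* dyp = dy.begin() + plane * (c + (size_t)C * b);
      for (size_t k = 0; k < plane; ++k) {
        sdy += dyp[k];
        sdyx += dyp[k] * (xp[k] - m) * istd;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double n = (double)plane * B;
    const double g = gamma[c] * istd;
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + plane * (c + (size_t)C * b);
      const double* dyp = dy.begin() + plane * (c + (size_t)C * b);
      double* dxp = dx.begin() + plane * (c + (size_t)C * b);
      for (size_t k = 0; k < plane; ++k) {
        const double xh = (xp[k] - m) * istd;
        dxp[k] = g * (dyp[k] - sdy / n - xh * sdyx / n);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inference-mode batch norm using running statistics.
// [[Rcpp::export(name = ".bn_eval")]]
NumericVector bn_eval(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar, double eps) {
  check_dim4(x);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y = num4(H, W, C, B);
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] / std::sqrt(rvar[c] + eps);
    const double sh = beta[c] - sc * rmean[c];
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + plane * (c + (size_t)C * b);
      double* yp = y.begin() + plane * (c + (size_t)C * b);
      for (size_t k = 0; k < plane; ++k) yp[k] = sc * xp[k] + sh;
    }
  }
  return y;
}
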