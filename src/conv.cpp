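// Convolution / pooling kernels for the miaug network engine.
// Array layout: activations (H, W, C, N), weights (k, k, C_in, C_out),
// all column-major doubles as produced by base R arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

// Gather kxk patches of one image into a (k*k*C) x (Ho*Wo) matrix.
static void im2col(const double* x, int H, int W, int C,
                   int k, int s, int p, arma::mat& cols) {
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(W, k, s, p);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      double* dst = cols.colptr(oi + (size_t)Ho * oj);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int ij = oj * s - p + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = oi * s - p + ki;
            dst[ki + k * kj + k * k * c] =
              (ii >= 0 && ii < H && ij >= 0 && ij < W)
                ? xc[ii + (size_t)ij * H] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int s, int p, double* x) {
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(W, k, s, p);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const double* src = cols.colptr(oi + (size_t)Ho * oj);
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int ij = oj * s - p + kj;
          if (ij < 0 || ij >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = oi * s - p + ki;
            if (ii < 0 || ii >= H) continue;
            xc[ii + (size_t)ij * H] += src[ki + k * kj + k * k * c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], F = dw[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat Wm(w.begin(), (size_t)k * k * C, F, false);
  arma::mat cols((size_t)k * k * C, (size_t)Ho * Wo);
  arma::rowvec bv(b.begin(), F, false);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat Yn(y.begin() + (size_t)n * Ho * Wo * F, (size_t)Ho * Wo, F, false, true);
    Yn = cols.t() * Wm;
    Yn.each_row() += bv;
  }
  return y;
}

// Gradient w.r.t. the convolution input (also the forward pass of a
// stride-s transposed convolution with the same weights).
// [[Rcpp::export(name = ".conv_bwd_input")]]
NumericVector conv_bwd_input(NumericVector dy, NumericVector w,
                             int stride, int pad, int H, int W) {
  IntegerVector dd = dy.attr("dim"), dw = w.attr("dim");
  const int Ho = dd[0], Wo = dd[1], F = dd[2], N = dd[3];
  const int k = dw[0], C = dw[2];
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat Wm(w.begin(), (size_t)k * k * C, F, false);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(dy.begin() + (size_t)n * Ho * Wo * F, (size_t)Ho * Wo, F, false);
    arma::mat dcols = Wm * dYn.t();
    col2im(dcols, H, W, C, k, stride, pad, dxv.begin() + (size_t)n * H * W * C);
  }
  return dxv;
}

// Gradient w.r.t. the convolution weights, summed over the batch.
// [[Rcpp::export(name = ".conv_bwd_weights")]]
NumericVector conv_bwd_weights(NumericVector x, NumericVector dy,
                               int k, int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dd = dy.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = dd[0], Wo = dd[1], F = dd[2];
  NumericVector dwv((size_t)k * k * C * F);
  dwv.attr("dim") = IntegerVector::create(k, k, C, F);
  arma::mat dW(dwv.begin(), (size_t)k * k * C, F, false, true);
  arma::mat cols((size_t)k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat dYn(dy.begin() + (size_t)n * Ho * Wo * F, (size_t)Ho * Wo, F, false);
    dW += cols * dYn;
  }
  return dwv;
}

// 2x2 (or size x size) non-overlapping max pooling; returns pooled values
// and the flat within-image argmax indices needed by the backward pass.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int size) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H / size, Wo = W / size;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int kj = 0; kj < size; ++kj) {
            for (int ki = 0; ki < size; ++ki) {
              const int ii = oi * size + ki, ij = oj * size + kj;
              const int fl = ii + ij * H + c * H * W;
              if (xc[ii + (size_t)ij * H] > best) {
                best = xc[ii + (size_t)ij * H];
                besti = fl;
              }
            }
          }
          // output written in (oi, oj, c) order per image
          const size_t pos = (size_t)n * Ho * Wo * C + (size_t)c * Ho * Wo +
                             (size_t)oj * Ho + oi;
          y[pos] = best;
          idx[pos] = besti;
          (void)o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx,
                          int H, int W) {
  IntegerVector dd = dy.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t per_out = (size_t)Ho * Wo * C, per_in = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    double* dxn = dxv.begin() + (size_t)n * per_in;
    const double* dyn = dy.begin() + (size_t)n * per_out;
    const int* in = idx.begin() + (size_t)n * per_out;
    for (size_t i = 0; i < per_out; ++i) dxn[in[i]] += dyn[i];
  }
  return dxv;
}
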