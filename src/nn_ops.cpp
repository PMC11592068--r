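// Low-level tensor ops for the CNN layers. All arrays use R's column-major
// layout with dims (H, W, C, N) for activations and (kh, kw, Cin, Cout) for
// kernels. Convolutions are im2col + BLAS GEMM; transpose convolution and
// max-pooling are direct loops (kernels here are tiny).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double *xp, int H, int W, int Cin, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int K = kh * kw * Cin;
  arma::mat cols(K, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (size_t)H * W * Cin * n;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double *cp = cols.colptr((size_t)oi + (size_t)Ho * oj + (size_t)Ho * Wo * n);
        for (int ci = 0; ci < Cin; ++ci) {
          const double *xc = xn + (size_t)H * W * ci;
          for (int kj = 0; kj < kw; ++kj) {
            const int wj = oj * stride + kj - pad;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int wi = oi * stride + ki - pad;
              if (wi < 0 || wi >= H) continue;
              cp[ki + kh * kj + kh * kw * ci] = xc[wi + (size_t)H * wj];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin;
  arma::mat cols = im2col(x.begin(), H, W, Cin, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat out = Wm.t() * cols; // (Cout, Ho*Wo*N)
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double *yp = y.begin();
  const size_t hw = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yc = yp + hw * co + hw * Cout * n;
      for (size_t p = 0; p < hw; ++p) yc[p] = out(co, p + hw * n);
    }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin;
  const size_t hw = (size_t)Ho * Wo;

  arma::mat cols = im2col(x.begin(), H, W, Cin, N, kh, kw, stride, pad, Ho, Wo);
  // gather dY as (Cout, Ho*Wo*N)
  arma::mat dYm(Cout, hw * N);
  const double *dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *dc = dp + hw * co + hw * Cout * n;
      for (size_t p = 0; p < hw; ++p) dYm(co, p + hw * n) = dc[p];
    }
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat dWm = cols * dYm.t();  // (K, Cout)
  arma::mat dcols = Wm * dYm;      // (K, Ho*Wo*N)

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dw.begin());

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double *xn = dxp + (size_t)H * W * Cin * n;
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        const double *cp = dcols.colptr((size_t)oi + (size_t)Ho * oj + hw * n);
        for (int ci = 0; ci < Cin; ++ci) {
          double *xc = xn + (size_t)H * W * ci;
          for (int kj = 0; kj < kw; ++kj) {
            const int wj = oj * stride + kj - pad;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int wi = oi * stride + ki - pad;
              if (wi < 0 || wi >= H) continue;
              xc[wi + (size_t)H * wj] += cp[ki + kh * kj + kh * kw * ci];
            }
          }
        }
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Transpose convolution, w dims (kh, kw, Cin, Cout):
// y[i*s+ki, j*s+kj, co] += x[i, j, ci] * w[ki, kj, ci, co]
// [[Rcpp::export]]
NumericVector convt2d_forward_cpp(NumericVector x, NumericVector w, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H - 1) * stride + kh, Wo = (W - 1) * stride + kw;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yc = yp + (size_t)Ho * Wo * co + (size_t)Ho * Wo * Cout * n;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xp + (size_t)H * W * ci + (size_t)H * W * Cin * n;
        const double *wc = wp + (size_t)kh * kw * ci + (size_t)kh * kw * Cin * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double xv = xc[i + (size_t)H * j];
            if (xv == 0.0) continue;
            for (int kj = 0; kj < kw; ++kj)
              for (int ki = 0; ki < kh; ++ki)
                yc[(i * stride + ki) + (size_t)Ho * (j * stride + kj)] +=
                  xv * wc[ki + kh * kj];
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List convt2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                          int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H - 1) * stride + kh, Wo = (W - 1) * stride + kw;
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = w.begin(), *dp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *dc = dp + (size_t)Ho * Wo * co + (size_t)Ho * Wo * Cout * n;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xp + (size_t)H * W * ci + (size_t)H * W * Cin * n;
        const double *wc = wp + (size_t)kh * kw * ci + (size_t)kh * kw * Cin * co;
        double *dxc = dxp + (size_t)H * W * ci + (size_t)H * W * Cin * n;
        double *dwc = dwp + (size_t)kh * kw * ci + (size_t)kh * kw * Cin * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double xv = xc[i + (size_t)H * j];
            double acc = 0.0;
            for (int kj = 0; kj < kw; ++kj)
              for (int ki = 0; ki < kh; ++ki) {
                const double g = dc[(i * stride + ki) + (size_t)Ho * (j * stride + kj)];
                acc += g * wc[ki + kh * kj];
                dwc[ki + kh * kj] += g * xv;
              }
            dxc[i + (size_t)H * j] += acc;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * c + (size_t)H * W * C * n;
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki) {
              const size_t li = base + (oi * stride + ki) + (size_t)H * (oj * stride + kj);
              if (xp[li] > best) { best = xp[li]; bidx = li; }
            }
          // y is traversed in its own storage order here
          const size_t oo = (size_t)oi + (size_t)Ho * oj + (size_t)Ho * Wo * c +
                            (size_t)Ho * Wo * C * n;
          yp[oo] = best;
          ip[oo] = (int)bidx;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  const double *dp = dy.begin();
  const int *ip = idx.begin();
  const size_t m = dy.size();
  for (size_t i = 0; i < m; ++i) dxp[ip[i]] += dp[i];
  return dx;
}
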