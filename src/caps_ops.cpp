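// Capsule-layer kernels: prediction-vector computation and the routing
// weight/input gradients. Layouts: W (Dc, D, N, K), u (D, N, B),
// uhat (Dc, N, K, B), ds (Dc, K, B), couplings (N, K, B).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector caps_uhat_cpp(NumericVector W, NumericVector u) {
  IntegerVector wd = W.attr("dim"), ud = u.attr("dim");
  const int Dc = wd[0], D = wd[1], N = wd[2], K = wd[3], B = ud[2];
  NumericVector uhat((size_t)Dc * N * K * B);
  uhat.attr("dim") = IntegerVector::create(Dc, N, K, B);
  const double *wp = W.begin(), *up = u.begin();
  double *hp = uhat.begin();
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < K; ++j)
      for (int i = 0; i < N; ++i) {
        const double *wb = wp + (size_t)Dc * D * (i + (size_t)N * j);
        const double *ub = up + (size_t)D * (i + (size_t)N * b);
        double *hb = hp + (size_t)Dc * (i + (size_t)N * (j + (size_t)K * b));
        for (int m = 0; m < Dc; ++m) {
          double acc = 0.0;
          for (int d = 0; d < D; ++d) acc += wb[m + (size_t)Dc * d] * ub[d];
          hb[m] = acc;
        }
      }
  return uhat;
}

// [[Rcpp::export]]
List caps_routing_grad_cpp(NumericVector W, NumericVector u,
                           NumericVector ds, NumericVector cc) {
  IntegerVector wd = W.attr("dim"), ud = u.attr("dim");
  const int Dc = wd[0], D = wd[1], N = wd[2], K = wd[3], B = ud[2];
  NumericVector dW((size_t)Dc * D * N * K), du((size_t)D * N * B);
  dW.attr("dim") = wd;
  du.attr("dim") = ud;
  const double *wp = W.begin(), *up = u.begin(), *dsp = ds.begin(),
               *cp = cc.begin();
  double *dwp = dW.begin(), *dup = du.begin();
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < K; ++j) {
      const double *dsb = dsp + (size_t)Dc * (j + (size_t)K * b);
      for (int i = 0; i < N; ++i) {
        const double coef = cp[i + (size_t)N * (j + (size_t)K * b)];
        if (coef == 0.0) continue;
        const double *wb = wp + (size_t)Dc * D * (i + (size_t)N * j);
        const double *ub = up + (size_t)D * (i + (size_t)N * b);
        double *dwb = dwp + (size_t)Dc * D * (i + (size_t)N * j);
        double *dub = dup + (size_t)D * (i + (size_t)N * b);
        for (int m = 0; m < Dc; ++m) {
          const double g = dsb[m] * coef;
          if (g == 0.0) continue;
          for (int d = 0; d < D; ++d) {
            dwb[m + (size_t)Dc * d] += g * ub[d];
            dub[d] += wb[m + (size_t)Dc * d] * g;
          }
        }
      }
    }
  return List::create(_["dW"] = dW, _["du"] = du);
}
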