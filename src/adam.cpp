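#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor. p, m and v are
// mutated directly; callers own these buffers (they are created by the
// network constructors and never shared with user-visible objects).
// lr_t is the bias-corrected step size lr * sqrt(1 - b2^t) / (1 - b1^t).
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector p, NumericVector g, NumericVector m,
                         NumericVector v, double lr_t, double b1, double b2,
                         double eps) {
  R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam buffers have mismatched lengths");
  double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    pp[i] -= lr_t * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}
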