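#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Gather a (C, L_in, B) input (column-major, channel fastest) into the
// im2col matrix (C*k, L_out*B) used by the GEMM convolution, with implicit
// zero padding of p on each side. Row order within a column: channel
// fastest inside each tap j, matching the C_out x (k*C_in) weight layout.
// [[Rcpp::export(name = ".im2col_pad")]]
NumericMatrix im2col_pad(NumericVector x, int C, int L_in, int B, int k,
                         int s, int p, int L_out) {
  NumericMatrix out(C * k, (R_xlen_t)L_out * B);
  const double *px = REAL(x);
  double *po = REAL(out);
  const R_xlen_t ck = (R_xlen_t)C * k;
  for (int b = 0; b < B; ++b) {
    const double *xb = px + (R_xlen_t)b * C * L_in;
    double *ob = po + (R_xlen_t)b * L_out * ck;
    for (int t = 0; t < L_out; ++t) {
      double *col = ob + (R_xlen_t)t * ck;
      for (int j = 0; j < k; ++j) {
        int q = t * s + j - p;        // source position
        if (q >= 0 && q < L_in)
          std::memcpy(col + (R_xlen_t)j * C, xb + (R_xlen_t)q * C,
                      C * sizeof(double));
        else
          std::memset(col + (R_xlen_t)j * C, 0, C * sizeof(double));
      }
    }
  }
  return out;
}

// Scatter-add the im2col gradient back onto the (C, L_in, B) input,
// dropping contributions that fell in the zero padding.
// [[Rcpp::export(name = ".col2im_pad")]]
NumericVector col2im_pad(NumericMatrix dXcol, int C, int L_in, int B, int k,
                         int s, int p, int L_out) {
  NumericVector dx((R_xlen_t)C * L_in * B);
  const double *pd = REAL(dXcol);
  double *po = REAL(dx);
  const R_xlen_t ck = (R_xlen_t)C * k;
  for (int b = 0; b < B; ++b) {
    double *xb = po + (R_xlen_t)b * C * L_in;
    const double *db = pd + (R_xlen_t)b * L_out * ck;
    for (int t = 0; t < L_out; ++t) {
      const double *col = db + (R_xlen_t)t * ck;
      for (int j = 0; j < k; ++j) {
        int q = t * s + j - p;
        if (q < 0 || q >= L_in) continue;
        double *dst = xb + (R_xlen_t)q * C;
        const double *src = col + (R_xlen_t)j * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L_in, B);
  return dx;
}
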