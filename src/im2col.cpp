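#include <Rcpp.h>
using namespace Rcpp;

// kernel-3, pad-1, stride-1 1D im2col for activations stored as (C, L, B).
// Output: (3C, L*B) matrix whose column (l, b) stacks x[, l-1, b], x[, l, b],
// x[, l+1, b] (zero at the edges).
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int c, int l, int b) {
  NumericMatrix out(3 * c, l * b);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int ib = 0; ib < b; ++ib) {
    for (int il = 0; il < l; ++il) {
      double* col = po + (R_xlen_t)(ib * l + il) * 3 * c;
      for (int k = 0; k < 3; ++k) {
        const int src_l = il + k - 1;
        if (src_l < 0 || src_l >= l) {
          for (int ic = 0; ic < c; ++ic) col[k * c + ic] = 0.0;
        } else {
          const double* src = px + (R_xlen_t)(ib * l + src_l) * c;
          for (int ic = 0; ic < c; ++ic) col[k * c + ic] = src[ic];
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: accumulate (3C, L*B) columns back into a (C, L, B)
// gradient array.
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix colmat, int c, int l, int b) {
  NumericVector out((R_xlen_t)c * l * b);
  const double* pc = REAL(colmat);
  double* po = REAL(out);
  for (int ib = 0; ib < b; ++ib) {
    for (int il = 0; il < l; ++il) {
      const double* col = pc + (R_xlen_t)(ib * l + il) * 3 * c;
      for (int k = 0; k < 3; ++k) {
        const int dst_l = il + k - 1;
        if (dst_l < 0 || dst_l >= l) continue;
        double* dst = po + (R_xlen_t)(ib * l + dst_l) * c;
        for (int ic = 0; ic < c; ++ic) dst[ic] += col[k * c + ic];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(c, l, b);
  return out;
}
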