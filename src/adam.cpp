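#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update for one parameter tensor. Modifies param, m and v
// (which are allocated once per tensor by the trainer, so in-place mutation
// is safe and avoids per-step allocation of multi-million-element vectors).
// [[Rcpp::export]]
void adam_step_cpp(NumericVector param, NumericVector grad,
                   NumericVector m, NumericVector v,
                   double lr, double beta1, double beta2,
                   double eps, int t) {
  const R_xlen_t n = param.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    stop("adam_step_cpp: size mismatch");
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = grad[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    param[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}
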