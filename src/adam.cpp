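#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update of one parameter array. `p`, `m` and `v` are owned
// exclusively by the model environment and are updated without copying;
// `g` is the freshly accumulated gradient of the current step.
// [[Rcpp::export(rng = false)]]
void adam_update(NumericVector p, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double b1, double b2,
                 double eps, int t) {
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
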