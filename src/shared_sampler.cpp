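// Collapsed slice chain for the shared-modulator GSM. After a one-time
// simultaneous diagonalization (done in R), the marginal log-density of
// the modulator is O(d) per evaluation:
//   log p(v | x) ~ -0.5 * [ sum log(v^2 D + 1) + sum y^2 / (v^2 D + 1) ]
//                  + Weibull log-prior + log-Jacobian (chain runs on log v)

#include <Rcpp.h>
#include <cmath>

namespace {

struct SharedModel {
  Rcpp::NumericVector D, y2;
  double shape, scale;

  double logpost(double u) const {
    double v = std::exp(u);
    double v2 = v * v, acc = 0.0;
    const int d = D.size();
    for (int j = 0; j < d; ++j) {
      double den = v2 * D[j] + 1.0;
      acc += std::log(den) + y2[j] / den;
    }
    double lp = std::log(shape / scale) +
      (shape - 1.0) * std::log(v / scale) - std::pow(v / scale, shape);
    return -0.5 * acc + lp + u;
  }
};

}  // namespace

// [[Rcpp::export(name = ".shared_v_chain_cpp")]]
Rcpp::NumericVector shared_v_chain_cpp(Rcpp::NumericVector D,
                                       Rcpp::NumericVector y2,
                                       double shape, double scale,
                                       int n_draws, int warmup,
                                       double u_init,
                                       double slice_width = 1.0) {
  SharedModel mod{D, y2, shape, scale};
  Rcpp::RNGScope rng;
  Rcpp::NumericVector out(n_draws);
  double u = u_init;
  for (int it = -warmup; it < n_draws; ++it) {
    double f0 = mod.logpost(u);
    double z = f0 - ::Rf_rexp(1.0);
    double lo = u - slice_width * ::unif_rand();
    double hi = lo + slice_width;
    for (int k = 0; k < 50 && mod.logpost(lo) > z; ++k) lo -= slice_width;
    for (int k = 0; k < 50 && mod.logpost(hi) > z; ++k) hi += slice_width;
    for (;;) {
      double u1 = lo + (hi - lo) * ::unif_rand();
      if (mod.logpost(u1) > z) { u = u1; break; }
      if (u1 < u) lo = u1; else hi = u1;
    }
    if (it >= 0) out[it] = std::exp(u);
  }
  return out;
}
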