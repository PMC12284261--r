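// Collapsed slice-within-Gibbs chain for the independent-modulator GSM.
// The two modulators are slice-sampled on the log scale under their exact
// marginal posterior p(v1, v2 | x) (features integrated out analytically);
// the features are then drawn from the Gaussian conditional p(g | v, x).
// Uses R's RNG so chains are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct Model {
  vec x;
  mat Sigma_g, Sigma_noise, Sg_inv, Sn_inv;
  mat G1, G2;                 // the two diagonal blocks of Sigma_g
  vec Sn_inv_x;
  double shape, scale;
  int m, d;

  void precompute() {
    G1 = Sigma_g.submat(0, 0, m - 1, m - 1);
    G2 = Sigma_g.submat(m, m, d - 1, d - 1);
  }

  // log p(v1, v2, x) up to a constant, v = exp(u), including the log
  // transform's Jacobian; Sigma_g is block-diagonal for this structure,
  // so V Sigma_g V only touches the two diagonal blocks
  double logpost(double u1, double u2) const {
    double v1 = std::exp(u1), v2 = std::exp(u2);
    mat S = Sigma_noise;
    S.submat(0, 0, m - 1, m - 1) += (v1 * v1) * G1;
    S.submat(m, m, d - 1, d - 1) += (v2 * v2) * G2;
    mat L;
    if (!chol(L, S, "lower")) return -datum::inf;
    vec z = solve(trimatl(L), x);
    double ll = -0.5 * d * std::log(2.0 * datum::pi) -
      accu(log(L.diag())) - 0.5 * dot(z, z);
    double lp = 0.0;
    for (double v : {v1, v2})
      lp += std::log(shape / scale) +
        (shape - 1.0) * std::log(v / scale) - std::pow(v / scale, shape);
    return ll + lp + u1 + u2;   // Jacobian dv/du = v
  }
};

// univariate slice sampler (stepping out + shrinkage) on one coordinate
double slice1(const Model& mod, double u0, double other, bool first,
              double w, int max_steps) {
  auto logf = [&](double u) {
    return first ? mod.logpost(u, other) : mod.logpost(other, u);
  };
  double f0 = logf(u0);
  double z = f0 - ::Rf_rexp(1.0);
  double lo = u0 - w * ::unif_rand();
  double hi = lo + w;
  for (int k = 0; k < max_steps && logf(lo) > z; ++k) lo -= w;
  for (int k = 0; k < max_steps && logf(hi) > z; ++k) hi += w;
  for (;;) {
    double u1 = lo + (hi - lo) * ::unif_rand();
    if (logf(u1) > z) return u1;
    if (u1 < u0) lo = u1; else hi = u1;
  }
}

}  // namespace

// [[Rcpp::export(name = ".indep_chain_cpp")]]
Rcpp::List indep_chain_cpp(const arma::vec& x,
                           const arma::mat& Sigma_g,
                           const arma::mat& Sigma_noise,
                           const arma::mat& Sg_inv,
                           const arma::mat& Sn_inv,
                           double shape, double scale, int m,
                           int n_draws, int warmup,
                           double u1_init, double u2_init,
                           double slice_width = 1.0,
                           Rcpp::Nullable<Rcpp::NumericMatrix> innovations =
                             R_NilValue) {
  Model mod;
  mod.x = x;
  mod.Sigma_g = Sigma_g;
  mod.Sigma_noise = Sigma_noise;
  mod.Sg_inv = Sg_inv;
  mod.Sn_inv = Sn_inv;
  mod.Sn_inv_x = Sn_inv * x;
  mod.shape = shape;
  mod.scale = scale;
  mod.m = m;
  mod.d = x.n_elem;
  mod.precompute();

  Rcpp::RNGScope rng;
  const int d = mod.d;
  mat g(n_draws, d), vdraws(n_draws, 2);
  mat Z;
  bool use_z = innovations.isNotNull();
  if (use_z) Z = Rcpp::as<arma::mat>(innovations.get());
  double u1 = u1_init, u2 = u2_init;

  for (int it = -warmup; it < n_draws; ++it) {
    u1 = slice1(mod, u1, u2, true, slice_width, 50);
    u2 = slice1(mod, u2, u1, false, slice_width, 50);
    if (it < 0) continue;
    double v1 = std::exp(u1), v2 = std::exp(u2);
    vec s(d);
    s.head(m).fill(v1);
    s.tail(m).fill(v2);
    mat P = Sg_inv + Sn_inv % (s * s.t());
    mat R = chol(P);                         // upper: P = R' R
    vec rhs = s % mod.Sn_inv_x;
    vec mean = solve(trimatu(R), solve(trimatl(R.t()), rhs));
    vec zn(d);
    if (use_z) zn = Z.row(it).t();
    else for (int j = 0; j < d; ++j) zn(j) = ::norm_rand();
    vec gi = mean + solve(trimatu(R), zn);
    g.row(it) = gi.t();
    vdraws(it, 0) = v1;
    vdraws(it, 1) = v2;
  }
  return Rcpp::List::create(Rcpp::Named("g") = g,
                            Rcpp::Named("v") = vdraws);
}
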