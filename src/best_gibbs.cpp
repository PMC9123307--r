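#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the two-group robust estimation model:
//   y_ji ~ t(nu, mu_j, sigma_j), j = 1,2 (shared nu)
// via the normal scale-mixture representation
//   y_ji | lambda_ji ~ N(mu_j, sigma_j^2 / lambda_ji),
//   lambda_ji ~ Gamma(nu/2, rate = nu/2).
// Priors (published BEST defaults): mu_j ~ N(mu0, mu_sd), sigma_j ~
// U(sigma_lo, sigma_hi), nu - 1 ~ Exp(rate = nu_rate) [mean 29 at 1/29].
// nu is updated by an adaptive random-walk Metropolis step on log(nu - 1)
// (tuned during burn-in only). Uses R's RNG, so set.seed() governs draws.

struct GroupState {
  const NumericVector& y;
  double mu, sigma;
  std::vector<double> lambda;
  GroupState(const NumericVector& y_, double mu_, double sigma_)
    : y(y_), mu(mu_), sigma(sigma_), lambda(y_.size(), 1.0) {}
};

static void update_lambda(GroupState& g, double nu) {
  const int n = g.y.size();
  for (int i = 0; i < n; ++i) {
    const double z = (g.y[i] - g.mu) / g.sigma;
    const double rate = (nu + z * z) / 2.0;
    g.lambda[i] = R::rgamma((nu + 1.0) / 2.0, 1.0 / rate);
  }
}

static void update_mu(GroupState& g, double mu0, double mu_sd) {
  const int n = g.y.size();
  double sl = 0.0, sly = 0.0;
  for (int i = 0; i < n; ++i) { sl += g.lambda[i]; sly += g.lambda[i] * g.y[i]; }
  const double s2 = g.sigma * g.sigma;
  const double prec = sl / s2 + 1.0 / (mu_sd * mu_sd);
  const double mean = (sly / s2 + mu0 / (mu_sd * mu_sd)) / prec;
  g.mu = R::rnorm(mean, std::sqrt(1.0 / prec));
}

static void update_sigma(GroupState& g, double lo, double hi) {
  const int n = g.y.size();
  double S = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = g.y[i] - g.mu;
    S += g.lambda[i] * d * d;
  }
  const double shape = (n - 1.0) / 2.0;
  if (shape <= 0.0 || S <= 0.0) return;  // degenerate; keep current value
  for (int tries = 0; tries < 50; ++tries) {
    const double gdraw = R::rgamma(shape, 2.0 / S);  // rate S/2
    const double sig = 1.0 / std::sqrt(gdraw);
    if (sig >= lo && sig <= hi) { g.sigma = sig; return; }
  }
}

static double nu_log_target(double nu, double nu_rate, int ntot,
                            double sum_log_lambda, double sum_lambda) {
  const double h = nu / 2.0;
  return ntot * (h * std::log(h) - R::lgammafn(h)) +
    (h - 1.0) * sum_log_lambda - h * sum_lambda - (nu - 1.0) * nu_rate;
}

// [[Rcpp::export]]
NumericMatrix cpp_best_gibbs(NumericVector y1, NumericVector y2,
                             int n_keep, int burn,
                             double mu0, double mu_sd,
                             double sigma_lo, double sigma_hi,
                             double nu_rate,
                             double mu1_init, double mu2_init,
                             double s1_init, double s2_init,
                             double nu_init) {
  GroupState g1(y1, mu1_init, s1_init), g2(y2, mu2_init, s2_init);
  double nu = nu_init;
  double prop_sd = 0.5;
  int acc = 0, tries = 0;
  const int ntot = y1.size() + y2.size();

  NumericMatrix out(n_keep, 5);
  for (int it = -burn; it < n_keep; ++it) {
    update_lambda(g1, nu); update_lambda(g2, nu);
    update_mu(g1, mu0, mu_sd); update_mu(g2, mu0, mu_sd);
    update_sigma(g1, sigma_lo, sigma_hi); update_sigma(g2, sigma_lo, sigma_hi);

    double sll = 0.0, sl = 0.0;
    for (double l : g1.lambda) { sll += std::log(l); sl += l; }
    for (double l : g2.lambda) { sll += std::log(l); sl += l; }
    // several Metropolis sweeps per scan: the random walk on log(nu - 1)
    // mixes much more slowly than the conjugate updates
    for (int rep = 0; rep < 5; ++rep) {
      const double eta = std::log(nu - 1.0);
      const double eta_new = eta + R::rnorm(0.0, prop_sd);
      const double nu_new = 1.0 + std::exp(eta_new);
      const double log_ratio =
        nu_log_target(nu_new, nu_rate, ntot, sll, sl) + eta_new -
        (nu_log_target(nu, nu_rate, ntot, sll, sl) + eta);
      ++tries;
      if (std::log(R::unif_rand()) < log_ratio) { nu = nu_new; ++acc; }
    }
    if (it < 0 && tries >= 50) {  // adapt toward ~44% acceptance in burn-in
      const double rate = static_cast<double>(acc) / tries;
      prop_sd *= std::exp(rate - 0.44);
      acc = 0; tries = 0;
    }
    if (it >= 0) {
      out(it, 0) = g1.mu; out(it, 1) = g2.mu;
      out(it, 2) = g1.sigma; out(it, 3) = g2.sigma;
      out(it, 4) = nu;
    }
  }
  return out;
}
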