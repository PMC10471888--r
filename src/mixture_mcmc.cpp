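#include <Rcpp.h>
using namespace Rcpp;

// Log density of a normal(mu, sigma) truncated to (0,1), evaluated at y in (0,1).
static inline double spike_logdens1(double y, double mu, double sigma) {
  double z = R::pnorm((1.0 - mu) / sigma, 0.0, 1.0, 1, 0) -
             R::pnorm((0.0 - mu) / sigma, 0.0, 1.0, 1, 0);
  return R::dnorm(y, mu, sigma, 1) - std::log(z);
}

// Marginal (allocation-summed) log likelihood: sum_i log(pi*f(y_i) + (1-pi)).
// The slab is U(0,1) so its density is 1 on the support.
static double marg_loglik(const NumericVector& y, double pi, double mu,
                          double sigma) {
  double ll = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    double f = std::exp(spike_logdens1(y[i], mu, sigma));
    ll += std::log(pi * f + (1.0 - pi));
  }
  return ll;
}

// Log likelihood of the spike cells only, given allocations z (1 = spike).
static double spike_loglik(const NumericVector& y, const IntegerVector& z,
                           double mu, double sigma) {
  double ll = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i)
    if (z[i] == 1) ll += spike_logdens1(y[i], mu, sigma);
  return ll;
}

static inline double reflect_into(double x, double lo, double hi) {
  double w = hi - lo;
  // fold onto [0, 2w) then reflect
  double t = x - lo, period = 2.0 * w;
  t -= std::floor(t / period) * period;
  return (t < w) ? lo + t : hi - (t - w);
}

// One-chain Gibbs/Metropolis sampler for the spike-and-slab mixture
//   Y ~ pi * N01(mu, sigma^2) + (1 - pi) * U(0,1)
//   pi ~ pi0 * delta0 + (1 - pi0) * U(0,1), pi0 ~ U(0,1)
// pi0 is integrated out analytically: the prior spike probability is 1/2.
// State: s in {0,1} (spike present), pi (0 iff s = 0), mu, sigma, z.
// Trans-model birth/death moves draw (pi, mu, sigma) from their priors and
// accept with the marginal-likelihood ratio, which is valid from any state.
// [[Rcpp::export]]
List mixture_mcmc_cpp(NumericVector y, int n_iter, int burn_in, int thin,
                      double mu_max, double sigma_rate, double mu_prop_sd,
                      double log_sigma_prop_sd) {
  const int n = y.size();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector out_pi(n_keep), out_mu(n_keep), out_sigma(n_keep);
  IntegerVector out_s(n_keep);

  // initial state from the prior
  int s = (R::unif_rand() < 0.5) ? 0 : 1;
  double pi = (s == 1) ? R::unif_rand() : 0.0;
  double mu = R::unif_rand() * mu_max;
  double sigma = R::exp_rand() / sigma_rate;
  IntegerVector z(n, 0);

  int acc_mu = 0, acc_sigma = 0, prop_mu = 0, prop_sigma = 0;
  int acc_trans = 0, prop_trans = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- trans-model move -------------------------------------------------
    // attempted with probability 1/2 so the s-chain stays aperiodic even
    // when the acceptance ratio is identically 1 (e.g. prior sampling)
    if (R::unif_rand() < 0.5) {
    ++prop_trans;
    if (s == 1) {
      // death: propose removing the spike; slab-only log likelihood is 0
      double log_alpha = -marg_loglik(y, pi, mu, sigma);
      if (std::log(R::unif_rand()) < log_alpha) {
        s = 0; pi = 0.0;
        std::fill(z.begin(), z.end(), 0);
        ++acc_trans;
      }
    } else {
      // birth: draw (pi, mu, sigma) from the priors
      double pi_p = R::unif_rand();
      double mu_p = R::unif_rand() * mu_max;
      double sig_p = R::exp_rand() / sigma_rate;
      double log_alpha = marg_loglik(y, pi_p, mu_p, sig_p);
      if (std::log(R::unif_rand()) < log_alpha) {
        s = 1; pi = pi_p; mu = mu_p; sigma = sig_p;
        ++acc_trans;
      }
    }
    }

    if (s == 1) {
      // --- allocations z_i | pi, mu, sigma --------------------------------
      int n_spike = 0;
      for (int i = 0; i < n; ++i) {
        double f = std::exp(spike_logdens1(y[i], mu, sigma));
        double p = pi * f / (pi * f + (1.0 - pi));
        z[i] = (R::unif_rand() < p) ? 1 : 0;
        n_spike += z[i];
      }
      // --- pi | z ~ Beta(n_spike + 1, n_slab + 1) -------------------------
      pi = R::rbeta(n_spike + 1.0, n - n_spike + 1.0);

      // --- mu | z, sigma: random-walk Metropolis reflected at [0, mu_max] --
      ++prop_mu;
      double mu_p = reflect_into(mu + R::norm_rand() * mu_prop_sd, 0.0, mu_max);
      double la = spike_loglik(y, z, mu_p, sigma) - spike_loglik(y, z, mu, sigma);
      if (std::log(R::unif_rand()) < la) { mu = mu_p; ++acc_mu; }

      // --- sigma | z, mu: Metropolis on log scale, Exp(rate) prior ---------
      ++prop_sigma;
      double sig_p = sigma * std::exp(R::norm_rand() * log_sigma_prop_sd);
      la = spike_loglik(y, z, mu, sig_p) - spike_loglik(y, z, mu, sigma)
         - sigma_rate * (sig_p - sigma)          // prior ratio
         + std::log(sig_p) - std::log(sigma);    // log-scale Jacobian
      if (std::log(R::unif_rand()) < la) { sigma = sig_p; ++acc_sigma; }
    } else {
      // s = 0: likelihood is free of (mu, sigma); full conditional = prior
      pi = 0.0;
      mu = R::unif_rand() * mu_max;
      sigma = R::exp_rand() / sigma_rate;
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      out_s[kept] = s; out_pi[kept] = pi;
      out_mu[kept] = mu; out_sigma[kept] = sigma;
      ++kept;
    }
  }

  return List::create(
    _["s"] = out_s, _["pi"] = out_pi, _["mu"] = out_mu, _["sigma"] = out_sigma,
    _["accept_mu"] = prop_mu ? (double)acc_mu / prop_mu : NA_REAL,
    _["accept_sigma"] = prop_sigma ? (double)acc_sigma / prop_sigma : NA_REAL,
    _["accept_trans"] = prop_trans ? (double)acc_trans / prop_trans : NA_REAL);
}

// Vectorised truncated-normal spike log density (shared with the R level so
// the sampler and the likelihood the user sees are one implementation).
// [[Rcpp::export]]
NumericVector spike_logdens_cpp(NumericVector y, double mu, double sigma) {
  const int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (y[i] <= 0.0 || y[i] >= 1.0) out[i] = R_NegInf;
    else out[i] = spike_logdens1(y[i], mu, sigma);
  }
  return out;
}

// Marginal log likelihood on a (pi-grid) x (mu,sigma-pair) lattice; used by
// the quadrature oracle. Returns an n_pi x n_pair matrix of
// sum_i log(pi_c * f(y_i; mu_ab, sigma_ab) + (1 - pi_c)).
// [[Rcpp::export]]
NumericMatrix grid_loglik_cpp(NumericVector y, NumericVector pi_grid,
                              NumericVector mu_vec, NumericVector sigma_vec) {
  const int n = y.size(), n_pi = pi_grid.size(), n_pair = mu_vec.size();
  NumericMatrix out(n_pi, n_pair);
  std::vector<double> f(n);
  for (int ab = 0; ab < n_pair; ++ab) {
    for (int i = 0; i < n; ++i)
      f[i] = std::exp(spike_logdens1(y[i], mu_vec[ab], sigma_vec[ab]));
    for (int c = 0; c < n_pi; ++c) {
      double pi = pi_grid[c], ll = 0.0;
      for (int i = 0; i < n; ++i) ll += std::log(pi * f[i] + (1.0 - pi));
      out(c, ab) = ll;
    }
  }
  return out;
}
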