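#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)) without overflow for |x| up to ~700
static inline double softplus(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// Bernoulli-logit log likelihood at linear predictor eta
static double bernoulli_loglik(const NumericVector& y,
                               const NumericVector& eta) {
  double ll = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) ll += y[i] * eta[i] - softplus(eta[i]);
  return ll;
}

// Log prior density (up to an additive constant) on the unconstrained,
// non-centered parameter vector theta = (alpha, beta[0..K-1], u = log sigma,
// z[0..J-1]) with b_j = sigma * z_j. The exponential prior on sigma carries
// the Jacobian term +u of the log transform, so sigma = 0 is unreachable;
// the z_j are a priori standard normal, independent of sigma, which keeps
// the sampler out of the funnel the centered parameterization creates.
static double log_prior_unc(const NumericVector& theta, int K, int J,
                            bool include_re, double im, double isd,
                            double csd, double rate) {
  double lp = R::dnorm(theta[0], im, isd, 1);
  for (int k = 0; k < K; ++k) lp += R::dnorm(theta[1 + k], 0.0, csd, 1);
  if (include_re) {
    const double u = theta[1 + K];
    const double sigma = std::exp(u);
    lp += std::log(rate) - rate * sigma + u;  // Exp(rate) on sigma + Jacobian
    for (int j = 0; j < J; ++j)
      lp += R::dnorm(theta[2 + K + j], 0.0, 1.0, 1);
  }
  return lp;
}

// Component-wise adaptive random-walk Metropolis for the hierarchical
// Bernoulli-logit model. One sweep updates every coordinate in turn;
// per-coordinate proposal scales adapt during warmup toward ~44%
// acceptance (the component-wise optimum) and are frozen afterwards.
//
// y:        0/1 outcomes
// X:        n x K covariate matrix (K may be 0)
// prov:     0-based province index per observation (ignored if !include_re)
// n_prov:   number of provinces J
// init:     starting unconstrained parameter vector
// Returns kept draws (n_iter x d), post-warmup acceptance rates per
// coordinate and for the two ridge moves, and the adapted proposal scales.
// [[Rcpp::export]]
List run_chain_cpp(NumericVector y, NumericMatrix X, IntegerVector prov,
                   int n_prov, double intercept_mean, double intercept_sd,
                   double coef_sd, double re_sd_rate, int n_warmup,
                   int n_iter, int thin, NumericVector init,
                   bool include_re) {
  const int n = y.size();
  const int K = X.ncol();
  const int J = include_re ? n_prov : 0;
  const int d = 1 + K + (include_re ? 1 + J : 0);
  if (init.size() != d) stop("init has wrong length");

  NumericVector theta = clone(init);
  double sigma_cur = include_re ? std::exp(theta[1 + K]) : 0.0;
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = theta[0];
    for (int k = 0; k < K; ++k) e += X(i, k) * theta[1 + k];
    if (include_re) e += sigma_cur * theta[2 + K + prov[i]];
    eta[i] = e;
  }
  double cur_ll = bernoulli_loglik(y, eta);
  double cur_lp = log_prior_unc(theta, K, J, include_re, intercept_mean,
                                intercept_sd, coef_sd, re_sd_rate);

  // last two slots: adaptive scales of the ridge moves (location, scale)
  const int n_moves = d + 2;
  NumericVector scale(n_moves, 0.5);
  IntegerVector acc_batch(n_moves, 0);
  IntegerVector acc_keep(n_moves, 0);
  NumericMatrix draws(n_iter, d);
  const int batch_len = 50;
  int batch_no = 0;
  const bool ridge = include_re && J > 0;

  NumericVector eta_prop(n);
  const int total = n_warmup + n_iter * thin;
  for (int it = 0; it < total; ++it) {
    const bool kept = it >= n_warmup;
    for (int jcoord = 0; jcoord < d; ++jcoord) {
      const double old = theta[jcoord];
      const double prop = old + scale[jcoord] * norm_rand();
      const double delta = prop - old;

      double new_ll = cur_ll;
      double sigma_prop = sigma_cur;
      bool eta_changed = false;
      if (jcoord == 0) {  // intercept shifts every eta
        for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + delta;
        eta_changed = true;
      } else if (jcoord <= K) {  // coefficient
        const int k = jcoord - 1;
        for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + delta * X(i, k);
        eta_changed = true;
      } else if (include_re && jcoord == 1 + K) {  // log sigma rescales all b
        sigma_prop = std::exp(prop);
        const double dsig = sigma_prop - sigma_cur;
        for (int i = 0; i < n; ++i)
          eta_prop[i] = eta[i] + dsig * theta[2 + K + prov[i]];
        eta_changed = true;
      } else if (include_re && jcoord >= 2 + K) {  // province z-score
        const int j = jcoord - 2 - K;
        for (int i = 0; i < n; ++i)
          eta_prop[i] = eta[i] + (prov[i] == j ? sigma_cur * delta : 0.0);
        eta_changed = true;
      }
      if (eta_changed) new_ll = bernoulli_loglik(y, eta_prop);

      theta[jcoord] = prop;
      const double new_lp = log_prior_unc(theta, K, J, include_re,
                                          intercept_mean, intercept_sd,
                                          coef_sd, re_sd_rate);
      const double log_ratio = (new_ll + new_lp) - (cur_ll + cur_lp);
      if (std::log(unif_rand()) < log_ratio) {
        cur_ll = new_ll;
        cur_lp = new_lp;
        sigma_cur = sigma_prop;
        if (eta_changed)
          for (int i = 0; i < n; ++i) eta[i] = eta_prop[i];
        acc_batch[jcoord] += 1;
        if (kept) acc_keep[jcoord] += 1;
      } else {
        theta[jcoord] = old;
      }
    }

    // Two extra moves exploit the model's likelihood-invariant directions:
    // with b = sigma * z the linear predictor depends on (alpha + sigma*z_j)
    // only, so translating alpha against z, or scaling sigma against z,
    // leaves the likelihood untouched and is accepted on the prior alone.
    // These carry the slow "ridge" directions that coordinate updates walk
    // in tiny steps.
    if (ridge) {
      {  // location ridge: alpha' = alpha + delta, z' = z - delta/sigma
        const double delta = scale[d] * norm_rand();
        const double a_new = theta[0] + delta;
        double log_ratio = R::dnorm(a_new, intercept_mean, intercept_sd, 1) -
                           R::dnorm(theta[0], intercept_mean, intercept_sd, 1);
        const double shift = delta / sigma_cur;
        for (int j = 0; j < J; ++j) {
          const double z_old = theta[2 + K + j];
          const double z_new = z_old - shift;
          log_ratio += 0.5 * (z_old * z_old - z_new * z_new);
        }
        if (std::log(unif_rand()) < log_ratio) {
          theta[0] = a_new;
          for (int j = 0; j < J; ++j) theta[2 + K + j] -= shift;
          cur_lp = log_prior_unc(theta, K, J, include_re, intercept_mean,
                                 intercept_sd, coef_sd, re_sd_rate);
          acc_batch[d] += 1;
          if (kept) acc_keep[d] += 1;
        }
      }
      {  // scale ridge: u' = u + delta, z' = z * exp(-delta); b unchanged.
         // Deterministic-map MH: acceptance carries the Jacobian exp(-J*delta).
        const double delta = scale[d + 1] * norm_rand();
        const double u_old = theta[1 + K];
        const double u_new = u_old + delta;
        const double s_new = std::exp(u_new);
        const double shrink = std::exp(-delta);
        double log_ratio = (-re_sd_rate * s_new + u_new) -
                           (-re_sd_rate * sigma_cur + u_old) -
                           J * delta;
        for (int j = 0; j < J; ++j) {
          const double z_old = theta[2 + K + j];
          const double z_new = z_old * shrink;
          log_ratio += 0.5 * (z_old * z_old - z_new * z_new);
        }
        if (std::log(unif_rand()) < log_ratio) {
          theta[1 + K] = u_new;
          for (int j = 0; j < J; ++j) theta[2 + K + j] *= shrink;
          sigma_cur = s_new;
          cur_lp = log_prior_unc(theta, K, J, include_re, intercept_mean,
                                 intercept_sd, coef_sd, re_sd_rate);
          acc_batch[d + 1] += 1;
          if (kept) acc_keep[d + 1] += 1;
        }
      }
    }

    if (!kept && ((it + 1) % batch_len == 0)) {
      batch_no += 1;
      const double step = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      for (int jcoord = 0; jcoord < n_moves; ++jcoord) {
        const double rate = acc_batch[jcoord] / (double)batch_len;
        scale[jcoord] *= std::exp(rate > 0.44 ? step : -step);
        acc_batch[jcoord] = 0;
      }
    }
    if (kept && ((it - n_warmup) % thin == thin - 1)) {
      const int row = (it - n_warmup) / thin;
      for (int jcoord = 0; jcoord < d; ++jcoord)
        draws(row, jcoord) = theta[jcoord];
    }
  }

  NumericVector acc_rate(d);
  for (int jcoord = 0; jcoord < d; ++jcoord)
    acc_rate[jcoord] = acc_keep[jcoord] / (double)(n_iter * thin);
  NumericVector ridge_rate(2);
  if (ridge) {
    ridge_rate[0] = acc_keep[d] / (double)(n_iter * thin);
    ridge_rate[1] = acc_keep[d + 1] / (double)(n_iter * thin);
  }

  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["ridge_rate"] = ridge_rate, _["scales"] = scale);
}
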