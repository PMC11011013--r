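#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the weighted mixture whole-genome
// regression y = mu + Z u delta + e, Var(e_i) = sigma_e^2 / w_i.
// The indicator delta_j is sampled from its full conditional with u_j
// integrated out analytically; u_j | delta_j = 1 is normal. BayesB
// keeps a locus-specific scaled-inverse-chi-square variance per marker
// (excluded loci draw from the prior); BayesC keeps one common marker
// variance. Uses R's RNG, so set.seed() in R governs reproducibility.
//
// Zc must arrive column-centered; w strictly positive.
// [[Rcpp::export]]
List bayes_wgr_mcmc(NumericMatrix Zc, NumericVector y, NumericVector w,
                    bool locus_variances, double pi,
                    int chain_length, int burn_in, int thin,
                    double nu_u, double scale_u,
                    double nu_e, double scale_e,
                    double init_sigma_u2, double init_sigma_e2,
                    bool fix_sigma_u, bool fix_sigma_e,
                    bool store_samples) {
  const int n = Zc.nrow(), k = Zc.ncol();
  const int n_retained = (chain_length - burn_in) / thin;

  std::vector<double> u(k, 0.0);
  std::vector<int> delta(k, 0);
  std::vector<double> sigma_u2_loc(locus_variances ? k : 0, init_sigma_u2);
  double sigma_u2 = init_sigma_u2;
  double sigma_e2 = init_sigma_e2;

  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  // weighted cross-products of each centered marker column
  std::vector<double> zwz(k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    const double *z = &Zc(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * z[i] * z[i];
    zwz[j] = s;
  }

  // residuals start at y - mu with mu at the weighted mean
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += w[i] * y[i];
  mu /= sw;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  const bool always_in = (pi <= 0.0);
  const double log_prior_odds = always_in ? 0.0 : std::log((1.0 - pi) / pi);

  std::vector<double> sum_u(k, 0.0);
  std::vector<double> freq(k, 0.0);
  double sum_mu = 0.0;
  NumericVector samp_sigma_u2(n_retained), samp_sigma_e2(n_retained),
      samp_n_incl(n_retained);
  NumericMatrix samples(store_samples ? k : 0,
                        store_samples ? n_retained : 0);
  int s_idx = 0;

  for (int t = 1; t <= chain_length; ++t) {
    // overall mean
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += w[i] * (r[i] + mu);
    double mu_new = rsum / sw + norm_rand() * std::sqrt(sigma_e2 / sw);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;

    // marker effects and indicators
    int n_incl = 0;
    double ss_u = 0.0;
    for (int j = 0; j < k; ++j) {
      const double *z = &Zc(0, j);
      if (delta[j]) {
        const double uj = u[j];
        for (int i = 0; i < n; ++i) r[i] += z[i] * uj;
      }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * z[i] * r[i];
      const double s2 = locus_variances ? sigma_u2_loc[j] : sigma_u2;
      const double C = zwz[j] + sigma_e2 / s2;
      bool include;
      if (always_in) {
        include = true;
      } else {
        const double log_odds = log_prior_odds
          + 0.5 * std::log(sigma_e2 / (s2 * C))
          + rhs * rhs / (2.0 * C * sigma_e2);
        const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        include = (unif_rand() < p1);
      }
      if (include) {
        const double uj = rhs / C + norm_rand() * std::sqrt(sigma_e2 / C);
        for (int i = 0; i < n; ++i) r[i] -= z[i] * uj;
        u[j] = uj;
        delta[j] = 1;
        ++n_incl;
        ss_u += uj * uj;
      } else {
        u[j] = 0.0;
        delta[j] = 0;
      }
      if (locus_variances && !fix_sigma_u) {
        const double df = nu_u + delta[j];
        sigma_u2_loc[j] = (nu_u * scale_u + u[j] * u[j]) / Rf_rchisq(df);
      }
    }
    if (!locus_variances && !fix_sigma_u) {
      sigma_u2 = (nu_u * scale_u + ss_u) / Rf_rchisq(nu_u + n_incl);
    }

    // residual variance with per-record weights
    if (!fix_sigma_e) {
      double ss_e = 0.0;
      for (int i = 0; i < n; ++i) ss_e += w[i] * r[i] * r[i];
      sigma_e2 = (nu_e * scale_e + ss_e) / Rf_rchisq(nu_e + n);
    }
    if (!R_finite(sigma_e2) || sigma_e2 <= 0.0 || sigma_e2 > 1e12) {
      stop("residual variance diverged at iteration %d", t);
    }

    if (t > burn_in && (t - burn_in) % thin == 0) {
      for (int j = 0; j < k; ++j) {
        sum_u[j] += u[j];
        freq[j] += delta[j];
        if (store_samples) samples(j, s_idx) = u[j];
      }
      sum_mu += mu;
      if (locus_variances) {
        double m = 0.0;
        for (int j = 0; j < k; ++j) m += sigma_u2_loc[j];
        samp_sigma_u2[s_idx] = m / k;
      } else {
        samp_sigma_u2[s_idx] = sigma_u2;
      }
      samp_sigma_e2[s_idx] = sigma_e2;
      samp_n_incl[s_idx] = n_incl;
      ++s_idx;
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector post_u(k), model_freq(k);
  for (int j = 0; j < k; ++j) {
    post_u[j] = sum_u[j] / n_retained;
    model_freq[j] = freq[j] / n_retained;
  }
  return List::create(
      _["posterior_mean"] = post_u,
      _["model_freq"] = model_freq,
      _["mu"] = sum_mu / n_retained,
      _["sigma_u2_samples"] = samp_sigma_u2,
      _["sigma_e2_samples"] = samp_sigma_e2,
      _["n_included_samples"] = samp_n_incl,
      _["retained"] = n_retained,
      _["samples"] = store_samples ? samples : NumericMatrix(0, 0));
}
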