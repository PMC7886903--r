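#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical negative-binomial count regression over ensemble members.
//
// Member j (one probable event-count sequence) contributes
//   y_jt ~ NB(mu_jt, phi),  log mu_jt = x_jt' beta_j
// with member-level coefficients pooled under top-level normals,
//   beta_jk ~ N(B_k, sigma_k),
// hyper-priors B_k ~ N(0, hyper_mean_sd^2), sigma_k ~ half-N(hyper_sd_scale),
// and a shared dispersion phi with half-normal prior on 1/phi.
//
// Sampler: random-walk Metropolis on each beta_jk, log(sigma_k) and
// log(phi), with Robbins-Monro adaptation of proposal scales during
// warmup; conjugate Gibbs draws for the hyper-means B_k. Uses R's RNG,
// so results are reproducible under set.seed().

static inline double nb_beta_term(double y, double eta, double mu, double phi) {
  // terms of the NB log pmf that involve eta (constants in y, phi dropped)
  return y * eta - (y + phi) * std::log(phi + mu);
}

// [[Rcpp::export(name = ".recm_sampler")]]
List recm_sampler(IntegerVector y, NumericMatrix X, IntegerVector member,
                  int M, int n_warmup, int n_save,
                  double hyper_mean_sd, double hyper_sd_scale,
                  double disp_inv_scale, double fixed_phi,
                  NumericVector beta_init, double phi_init) {
  const int N = y.size();
  const int P = X.ncol();
  const bool estimate_phi = !NumericVector::is_na(fixed_phi) ? false : true;

  // observations must arrive sorted by member (1-based); locate slices
  std::vector<int> start(M), fin(M);
  {
    std::vector<int> cnt(M, 0);
    for (int i = 0; i < N; ++i) cnt[member[i] - 1]++;
    int pos = 0;
    for (int j = 0; j < M; ++j) { start[j] = pos; pos += cnt[j]; fin[j] = pos; }
    for (int i = 1; i < N; ++i) {
      if (member[i] < member[i - 1]) stop("observations must be sorted by member");
    }
  }

  // state
  NumericMatrix beta(M, P);
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < P; ++k) beta(j, k) = beta_init[k];
  NumericVector B(P, 0.0), sigma(P, 0.5);
  double phi = estimate_phi ? phi_init : fixed_phi;

  std::vector<double> eta(N), mu(N);
  for (int i = 0; i < N; ++i) {
    double e = 0.0;
    for (int k = 0; k < P; ++k) e += X(i, k) * beta(member[i] - 1, k);
    eta[i] = e; mu[i] = std::exp(e);
  }

  // proposal scales (log) and acceptance bookkeeping
  NumericMatrix ls_beta(M, P);
  std::fill(ls_beta.begin(), ls_beta.end(), std::log(0.1));
  NumericVector ls_sigma(P, std::log(0.3));
  NumericVector ls_ncB(P, std::log(0.1)), ls_ncS(P, std::log(0.3));
  double ls_phi = std::log(0.3);
  const double target = 0.44;

  // storage
  NumericMatrix out_B(n_save, P), out_sigma(n_save, P);
  NumericMatrix out_beta(n_save, M * P);
  NumericVector out_phi(n_save);
  NumericMatrix acc_beta(M, P);
  double acc_phi = 0.0;
  NumericVector acc_sigma(P, 0.0);

  const int n_iter = n_warmup + n_save;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_warmup;
    const double rm = 1.0 / std::sqrt((double)(it + 1));

    // --- member-level coefficients: componentwise random-walk MH ---
    for (int j = 0; j < M; ++j) {
      for (int k = 0; k < P; ++k) {
        const double old = beta(j, k);
        const double prop = old + R::rnorm(0.0, std::exp(ls_beta(j, k)));
        const double dx = prop - old;
        double dll = 0.0;
        for (int i = start[j]; i < fin[j]; ++i) {
          const double eta_new = eta[i] + dx * X(i, k);
          const double mu_new = std::exp(eta_new);
          dll += nb_beta_term(y[i], eta_new, mu_new, phi)
               - nb_beta_term(y[i], eta[i], mu[i], phi);
        }
        dll += R::dnorm(prop, B[k], sigma[k], 1) -
               R::dnorm(old, B[k], sigma[k], 1);
        const bool accept = std::log(R::unif_rand()) < dll;
        if (accept) {
          beta(j, k) = prop;
          for (int i = start[j]; i < fin[j]; ++i) {
            eta[i] += dx * X(i, k);
            mu[i] = std::exp(eta[i]);
          }
        }
        if (adapting) {
          ls_beta(j, k) += rm * ((accept ? 1.0 : 0.0) - target);
        } else if (accept) {
          acc_beta(j, k) += 1.0;
        }
      }
    }

    // --- hyper-means: conjugate normal Gibbs ---
    for (int k = 0; k < P; ++k) {
      double sum_b = 0.0;
      for (int j = 0; j < M; ++j) sum_b += beta(j, k);
      const double prec = M / (sigma[k] * sigma[k]) +
                          1.0 / (hyper_mean_sd * hyper_mean_sd);
      const double mean = (sum_b / (sigma[k] * sigma[k])) / prec;
      B[k] = R::rnorm(mean, std::sqrt(1.0 / prec));
    }

    // --- hyper-sds: MH on log(sigma_k), half-normal prior ---
    for (int k = 0; k < P; ++k) {
      const double old = sigma[k];
      const double prop = old * std::exp(R::rnorm(0.0, std::exp(ls_sigma[k])));
      double dll = 0.0;
      for (int j = 0; j < M; ++j) {
        dll += R::dnorm(beta(j, k), B[k], prop, 1) -
               R::dnorm(beta(j, k), B[k], old, 1);
      }
      // half-normal prior + log-scale Jacobian
      dll += -(prop * prop - old * old) / (2.0 * hyper_sd_scale * hyper_sd_scale);
      dll += std::log(prop) - std::log(old);
      const bool accept = std::log(R::unif_rand()) < dll;
      if (accept) sigma[k] = prop;
      if (adapting) ls_sigma[k] += rm * ((accept ? 1.0 : 0.0) - target);
      else if (accept) acc_sigma[k] += 1.0;
    }

    // --- interweaved non-centred update of (B_k, log sigma_k) ---
    // Holding the standardized member offsets u_j = (beta_jk - B_k)/sigma_k
    // fixed, propose the pair jointly; this walks the hyper-parameters
    // through the funnel that the centred updates cannot traverse.
    for (int k = 0; k < P; ++k) {
      for (int which = 0; which < 2; ++which) {
        const double B_old = B[k], s_old = sigma[k];
        double B_new = B_old, s_new = s_old;
        if (which == 0) {
          B_new = B_old + R::rnorm(0.0, std::exp(ls_ncB[k]));
        } else {
          s_new = s_old * std::exp(R::rnorm(0.0, std::exp(ls_ncS[k])));
        }
        double dll = 0.0;
        std::vector<double> dx(M);
        for (int j = 0; j < M; ++j) {
          const double u = (beta(j, k) - B_old) / s_old;
          dx[j] = (B_new + s_new * u) - beta(j, k);
        }
        for (int i = 0; i < N; ++i) {
          const double eta_new = eta[i] + dx[member[i] - 1] * X(i, k);
          const double mu_new = std::exp(eta_new);
          dll += nb_beta_term(y[i], eta_new, mu_new, phi)
               - nb_beta_term(y[i], eta[i], mu[i], phi);
        }
        dll += R::dnorm(B_new, 0.0, hyper_mean_sd, 1) -
               R::dnorm(B_old, 0.0, hyper_mean_sd, 1);
        dll += -(s_new * s_new - s_old * s_old) /
               (2.0 * hyper_sd_scale * hyper_sd_scale);
        dll += std::log(s_new) - std::log(s_old); // Jacobian, log-scale walk
        const bool accept = std::log(R::unif_rand()) < dll;
        if (accept) {
          B[k] = B_new; sigma[k] = s_new;
          for (int j = 0; j < M; ++j) beta(j, k) += dx[j];
          for (int i = 0; i < N; ++i) {
            eta[i] += dx[member[i] - 1] * X(i, k);
            mu[i] = std::exp(eta[i]);
          }
        }
        if (adapting) {
          if (which == 0) ls_ncB[k] += rm * ((accept ? 1.0 : 0.0) - target);
          else ls_ncS[k] += rm * ((accept ? 1.0 : 0.0) - target);
        }
      }
    }

    // --- dispersion: MH on log(phi), half-normal prior on 1/phi ---
    if (estimate_phi) {
      const double old = phi;
      const double prop = old * std::exp(R::rnorm(0.0, std::exp(ls_phi)));
      double dll = 0.0;
      for (int i = 0; i < N; ++i) {
        dll += R::lgammafn(y[i] + prop) - R::lgammafn(prop)
             + prop * std::log(prop) - (y[i] + prop) * std::log(prop + mu[i])
             - (R::lgammafn(y[i] + old) - R::lgammafn(old)
                + old * std::log(old) - (y[i] + old) * std::log(old + mu[i]));
      }
      const double inv_new = 1.0 / prop, inv_old = 1.0 / old;
      dll += -(inv_new * inv_new - inv_old * inv_old) /
             (2.0 * disp_inv_scale * disp_inv_scale);
      // Jacobian of 1/phi w.r.t. log(phi) is 1/phi
      dll += std::log(inv_new) - std::log(inv_old);
      const bool accept = std::log(R::unif_rand()) < dll;
      if (accept) phi = prop;
      if (adapting) ls_phi += rm * ((accept ? 1.0 : 0.0) - target);
      else if (accept) acc_phi += 1.0;
    }

    // --- store ---
    if (!adapting) {
      const int s = it - n_warmup;
      for (int k = 0; k < P; ++k) {
        out_B(s, k) = B[k];
        out_sigma(s, k) = sigma[k];
      }
      for (int j = 0; j < M; ++j)
        for (int k = 0; k < P; ++k) out_beta(s, j + M * k) = beta(j, k);
      out_phi[s] = phi;
    }

    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  const double denom = (double)n_save;
  return List::create(
    _["B"] = out_B, _["sigma"] = out_sigma, _["beta"] = out_beta,
    _["phi"] = out_phi,
    _["accept_beta"] = acc_beta / denom,
    _["accept_sigma"] = acc_sigma / denom,
    _["accept_phi"] = acc_phi / denom);
}
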