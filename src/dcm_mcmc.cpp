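// Adaptive Metropolis-within-Gibbs sampler for the hierarchical conditional
// multinomial-logit discrete-choice model.
//
// Parameters (hierarchical): mu[k,s], sigma[k,s] (population mean / sd per
// covariate k and season s) and beta[g,k] (coefficients per covey-season
// group g). mu is updated by its exact conjugate Gibbs draw; beta and
// log(sigma) by adaptive random-walk Metropolis (target acceptance 0.44,
// adaptation confined to burn-in). Non-hierarchical mode drops beta/sigma
// and treats mu[k,s] as the shared coefficient, updated by random walk.
//
// Utilities and per-set log-likelihoods are maintained incrementally: a
// proposal on one coefficient touches only its group's sets and one
// covariate slice of the utility matrix.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double set_loglik(const double* u, int chosen) {
  double m = u[0];
  for (int a = 1; a < 4; ++a) if (u[a] > m) m = u[a];
  double s = 0.0;
  for (int a = 0; a < 4; ++a) s += std::exp(u[a] - m);
  return u[chosen] - m - std::log(s);
}

// [[Rcpp::export]]
NumericMatrix dcm_mcmc_chain(NumericVector Zflat, int n_sets, int K,
                             IntegerVector chosen, IntegerVector set_group,
                             IntegerVector set_season,
                             IntegerVector group_season, int n_groups,
                             bool hierarchical, int n_iter, int burn,
                             int thin, double prior_mu_sd,
                             double prior_sigma_sd, NumericMatrix mu_init,
                             NumericMatrix sigma_init,
                             NumericMatrix beta_init) {
  const double mu_prec = 1.0 / (prior_mu_sd * prior_mu_sd);
  // Z(alt, set, k) = Zflat[alt + 4*set + 4*n_sets*k]
  auto Z = [&](int a, int i, int k) -> double {
    return Zflat[a + 4 * i + 4 * n_sets * k];
  };

  std::vector<std::vector<int> > g_sets(std::max(n_groups, 1));
  std::vector<std::vector<int> > s_sets(2);
  for (int i = 0; i < n_sets; ++i) {
    if (hierarchical) g_sets[set_group[i]].push_back(i);
    s_sets[set_season[i]].push_back(i);
  }
  std::vector<std::vector<int> > s_groups(2);
  for (int g = 0; g < n_groups; ++g) s_groups[group_season[g]].push_back(g);

  // state
  std::vector<double> mu(2 * K), sigma(2 * K), beta((size_t)n_groups * K);
  for (int s = 0; s < 2; ++s)
    for (int k = 0; k < K; ++k) {
      mu[k + K * s] = mu_init(k, s);
      sigma[k + K * s] = sigma_init(k, s);
    }
  for (int g = 0; g < n_groups; ++g)
    for (int k = 0; k < K; ++k) beta[(size_t)g * K + k] = beta_init(g, k);

  std::vector<double> U((size_t)n_sets * 4, 0.0), ll(n_sets, 0.0);
  for (int i = 0; i < n_sets; ++i) {
    for (int a = 0; a < 4; ++a) {
      double u = 0.0;
      for (int k = 0; k < K; ++k) {
        double b = hierarchical ? beta[(size_t)set_group[i] * K + k]
                                : mu[k + K * set_season[i]];
        u += b * Z(a, i, k);
      }
      U[(size_t)i * 4 + a] = u;
    }
    ll[i] = set_loglik(&U[(size_t)i * 4], chosen[i]);
  }

  // adaptive scales
  std::vector<double> sc_beta((size_t)std::max(n_groups, 1) * K, 0.5);
  std::vector<double> sc_sigma(2 * K, 0.5), sc_mu(2 * K, 0.5),
      sc_shift(2 * K, 0.2), sc_scale(2 * K, 0.3);
  std::vector<int> acc_beta(sc_beta.size(), 0), acc_sigma(2 * K, 0),
      acc_mu(2 * K, 0), acc_shift(2 * K, 0), acc_scale(2 * K, 0);
  const int batch = 50;

  int n_par = hierarchical ? (2 * K + 2 * K + n_groups * K) : (2 * K);
  int n_keep = (n_iter - burn) / thin;
  NumericMatrix out(n_keep, n_par);
  int kept = 0;

  RNGScope scope;
  double unew[4];

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (hierarchical) {
      // beta: random-walk MH, one coordinate at a time
      for (int g = 0; g < n_groups; ++g) {
        int s = group_season[g];
        for (int k = 0; k < K; ++k) {
          size_t bi = (size_t)g * K + k;
          double b0 = beta[bi];
          double db = sc_beta[bi] * norm_rand();
          double b1 = b0 + db;
          double sig = sigma[k + K * s], m = mu[k + K * s];
          double lacc = (-(b1 - m) * (b1 - m) + (b0 - m) * (b0 - m)) /
                        (2.0 * sig * sig);
          std::vector<int>& sets = g_sets[g];
          // likelihood delta
          std::vector<double> newll(sets.size());
          for (size_t t = 0; t < sets.size(); ++t) {
            int i = sets[t];
            for (int a = 0; a < 4; ++a)
              unew[a] = U[(size_t)i * 4 + a] + db * Z(a, i, k);
            newll[t] = set_loglik(unew, chosen[i]);
            lacc += newll[t] - ll[i];
          }
          if (std::log(unif_rand()) < lacc) {
            beta[bi] = b1;
            for (size_t t = 0; t < sets.size(); ++t) {
              int i = sets[t];
              for (int a = 0; a < 4; ++a)
                U[(size_t)i * 4 + a] += db * Z(a, i, k);
              ll[i] = newll[t];
            }
            acc_beta[bi]++;
          }
        }
      }
      // mu: exact conjugate Gibbs draw given beta and sigma
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) {
          double sig = sigma[k + K * s];
          double sum = 0.0;
          int n = (int)s_groups[s].size();
          for (int t = 0; t < n; ++t)
            sum += beta[(size_t)s_groups[s][t] * K + k];
          double prec = mu_prec + n / (sig * sig);
          double mean = (sum / (sig * sig)) / prec;
          mu[k + K * s] = mean + norm_rand() / std::sqrt(prec);
        }
      // translation move: shift mu[k,s] and every beta[g,k] of season s
      // together. The beta | mu prior is invariant under the shift, so the
      // acceptance ratio involves only the likelihood (covariate slice k of
      // the season's sets) and the mu prior. Breaks the slow random-walk
      // coupling between a population mean and its group coefficients.
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) {
          int idx = k + K * s;
          double dm = sc_shift[idx] * norm_rand();
          double m0 = mu[idx], m1 = m0 + dm;
          double lacc = (m0 * m0 - m1 * m1) * 0.5 * mu_prec;
          std::vector<int>& sets = s_sets[s];
          std::vector<double> newll(sets.size());
          for (size_t t = 0; t < sets.size(); ++t) {
            int i = sets[t];
            for (int a = 0; a < 4; ++a)
              unew[a] = U[(size_t)i * 4 + a] + dm * Z(a, i, k);
            newll[t] = set_loglik(unew, chosen[i]);
            lacc += newll[t] - ll[i];
          }
          if (std::log(unif_rand()) < lacc) {
            mu[idx] = m1;
            for (int t = 0; t < (int)s_groups[s].size(); ++t)
              beta[(size_t)s_groups[s][t] * K + k] += dm;
            for (size_t t = 0; t < sets.size(); ++t) {
              int i = sets[t];
              for (int a = 0; a < 4; ++a)
                U[(size_t)i * 4 + a] += dm * Z(a, i, k);
              ll[i] = newll[t];
            }
            acc_shift[idx]++;
          }
        }
      // scale move: sigma[k,s] <- sigma * e^d with every beta[g,k] of the
      // season rescaled about mu: beta' = mu + (beta - mu) e^d. The
      // beta-prior and transform-Jacobian terms cancel, leaving the
      // likelihood delta, the sigma prior and the log-scale Jacobian.
      // Attacks the funnel coupling between sigma and its coefficients.
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) {
          int idx = k + K * s;
          double dd = sc_scale[idx] * norm_rand();
          double e = std::exp(dd);
          double s0 = sigma[idx], s1 = s0 * e, m = mu[idx];
          double lacc =
              (s0 * s0 - s1 * s1) / (2.0 * prior_sigma_sd * prior_sigma_sd) +
              dd;
          std::vector<int>& sets = s_sets[s];
          std::vector<double> newll(sets.size());
          for (size_t t = 0; t < sets.size(); ++t) {
            int i = sets[t];
            double db = (e - 1.0) *
                        (beta[(size_t)set_group[i] * K + k] - m);
            for (int a = 0; a < 4; ++a)
              unew[a] = U[(size_t)i * 4 + a] + db * Z(a, i, k);
            newll[t] = set_loglik(unew, chosen[i]);
            lacc += newll[t] - ll[i];
          }
          if (std::log(unif_rand()) < lacc) {
            sigma[idx] = s1;
            for (size_t t = 0; t < sets.size(); ++t) {
              int i = sets[t];
              double db = (e - 1.0) *
                          (beta[(size_t)set_group[i] * K + k] - m);
              for (int a = 0; a < 4; ++a)
                U[(size_t)i * 4 + a] += db * Z(a, i, k);
              ll[i] = newll[t];
            }
            for (int t = 0; t < (int)s_groups[s].size(); ++t) {
              size_t bi = (size_t)s_groups[s][t] * K + k;
              beta[bi] = m + (beta[bi] - m) * e;
            }
            acc_scale[idx]++;
          }
        }
      // sigma: random walk on log scale, half-Normal prior
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) {
          int idx = k + K * s;
          double s0 = sigma[idx];
          double ls1 = std::log(s0) + sc_sigma[idx] * norm_rand();
          double s1 = std::exp(ls1);
          double m = mu[idx];
          double lacc =
              (s0 * s0 - s1 * s1) / (2.0 * prior_sigma_sd * prior_sigma_sd) +
              std::log(s1) - std::log(s0);  // prior + log-scale Jacobian
          int n = (int)s_groups[s].size();
          for (int t = 0; t < n; ++t) {
            double b = beta[(size_t)s_groups[s][t] * K + k];
            double d = b - m;
            lacc += -std::log(s1) - d * d / (2.0 * s1 * s1) +
                    std::log(s0) + d * d / (2.0 * s0 * s0);
          }
          if (std::log(unif_rand()) < lacc) {
            sigma[idx] = s1;
            acc_sigma[idx]++;
          }
        }
    } else {
      // non-hierarchical: mu is the shared coefficient, random-walk MH
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) {
          int idx = k + K * s;
          double m0 = mu[idx];
          double dm = sc_mu[idx] * norm_rand();
          double m1 = m0 + dm;
          double lacc = (m0 * m0 - m1 * m1) * 0.5 * mu_prec;
          std::vector<int>& sets = s_sets[s];
          std::vector<double> newll(sets.size());
          for (size_t t = 0; t < sets.size(); ++t) {
            int i = sets[t];
            for (int a = 0; a < 4; ++a)
              unew[a] = U[(size_t)i * 4 + a] + dm * Z(a, i, k);
            newll[t] = set_loglik(unew, chosen[i]);
            lacc += newll[t] - ll[i];
          }
          if (std::log(unif_rand()) < lacc) {
            mu[idx] = m1;
            for (size_t t = 0; t < sets.size(); ++t) {
              int i = sets[t];
              for (int a = 0; a < 4; ++a)
                U[(size_t)i * 4 + a] += dm * Z(a, i, k);
              ll[i] = newll[t];
            }
            acc_mu[idx]++;
          }
        }
    }

    // diminishing adaptation, burn-in only
    if (iter <= burn && iter % batch == 0) {
      double step = std::min(0.25, 2.0 / std::sqrt((double)iter / batch));
      for (size_t j = 0; j < sc_beta.size(); ++j) {
        double r = (double)acc_beta[j] / batch;
        sc_beta[j] *= std::exp(step * (r - 0.44));
        acc_beta[j] = 0;
      }
      for (int j = 0; j < 2 * K; ++j) {
        double rs = (double)acc_sigma[j] / batch;
        sc_sigma[j] *= std::exp(step * (rs - 0.44));
        acc_sigma[j] = 0;
        double rm = (double)acc_mu[j] / batch;
        sc_mu[j] *= std::exp(step * (rm - 0.44));
        acc_mu[j] = 0;
        double rt = (double)acc_shift[j] / batch;
        sc_shift[j] *= std::exp(step * (rt - 0.44));
        acc_shift[j] = 0;
        double rc = (double)acc_scale[j] / batch;
        sc_scale[j] *= std::exp(step * (rc - 0.44));
        acc_scale[j] = 0;
      }
    }

    if (iter > burn && (iter - burn) % thin == 0 && kept < n_keep) {
      int col = 0;
      for (int s = 0; s < 2; ++s)
        for (int k = 0; k < K; ++k) out(kept, col++) = mu[k + K * s];
      if (hierarchical) {
        for (int s = 0; s < 2; ++s)
          for (int k = 0; k < K; ++k) out(kept, col++) = sigma[k + K * s];
        for (int g = 0; g < n_groups; ++g)
          for (int k = 0; k < K; ++k) out(kept, col++) = beta[(size_t)g * K + k];
      }
      kept++;
    }
  }
  return out;
}
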