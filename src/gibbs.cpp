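#include <Rcpp.h>
using namespace Rcpp;

// One full-conditional Gibbs sampler for the collapsed family model
//
//   y_ij = mu + X c + beta1 (alpha[r] D_r + alpha[s] D_s)
//               + beta2 (gamma[r] GE_r + gamma[s] GE_s) + phi_i + eps_ij
//
// with alpha_k, gamma_k ~ Bern(p_k), Bern(q_k); p_k, q_k ~ Beta(1,1);
// mu, beta1, beta2, c ~ N(0, sigma2_beta); phi_i ~ N(0, sigma2_phi);
// sigma2_phi, sigma2_eps ~ InvGamma(ig_a, ig_b).  Index 0 is the
// pseudolocus: alpha[0] = gamma[0] = 0 always and D = GE = 0 there.
//
// Every conditional is conjugate, so the sweep is exact Gibbs (detailed
// balance w.r.t. the joint).  All randomness comes from R's RNG, so
// set.seed() on the R side gives bit-reproducible chains.

static inline double rinvgamma(double shape, double rate) {
  // X ~ InvGamma(shape, rate)  <=>  1/X ~ Gamma(shape, rate)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".gibbs_cpp")]]
List gibbs_cpp(NumericVector y,
               IntegerVector fam,        // 0-based family index per offspring
               int M,                    // number of families
               NumericMatrix X,          // N x C covariate matrix (C may be 0)
               IntegerVector r,          // collapse index in 0..K per offspring
               IntegerVector s,
               NumericVector Dr, NumericVector Ds,     // deviations at r, s
               NumericVector GEr, NumericVector GEs,   // expectations at r, s
               int K,
               int iterations, int burn_in, int thin,
               double sigma2_beta,
               double ig_a, double ig_b,
               List init,
               int clamp_alpha,          // -1 free, 0 all-zero, 1 all-one
               int clamp_gamma,
               bool clamp_beta,          // force beta1 = beta2 = 0 (null pilot)
               bool include_phi,
               bool include_mu,
               double fix_sigma2_eps) {  // > 0 fixes sigma2_eps at that value

  const int N = y.size();
  const int C = X.ncol();

  // --- state -------------------------------------------------------------
  double mu      = as<double>(init["mu"]);
  double beta1   = as<double>(init["beta1"]);
  double beta2   = as<double>(init["beta2"]);
  NumericVector cvec = clone(as<NumericVector>(init["covar_coef"]));
  NumericVector phi  = clone(as<NumericVector>(init["phi"]));
  double s2phi   = as<double>(init["sigma2_phi"]);
  double s2eps   = as<double>(init["sigma2_eps"]);
  // alpha/gamma padded with pseudolocus at index 0 (always 0)
  IntegerVector alpha(K + 1, 0), gamma(K + 1, 0);
  {
    IntegerVector a0 = init["alpha"], g0 = init["gamma"];
    for (int k = 0; k < K; ++k) { alpha[k + 1] = a0[k]; gamma[k + 1] = g0[k]; }
  }
  if (clamp_alpha >= 0) for (int k = 1; k <= K; ++k) alpha[k] = clamp_alpha;
  if (clamp_gamma >= 0) for (int k = 1; k <= K; ++k) gamma[k] = clamp_gamma;
  if (clamp_beta) { beta1 = 0.0; beta2 = 0.0; }
  if (!include_mu) mu = 0.0;
  NumericVector p(K + 1, 0.5), q(K + 1, 0.5);

  // --- per-locus offspring lists (who references locus k via r or via s) --
  std::vector<std::vector<int> > idxR(K + 1), idxS(K + 1);
  for (int j = 0; j < N; ++j) {
    if (r[j] > 0) idxR[r[j]].push_back(j);
    if (s[j] > 0) idxS[s[j]].push_back(j);
  }

  // --- family offspring lists --------------------------------------------
  std::vector<std::vector<int> > famIdx(M);
  for (int j = 0; j < N; ++j) famIdx[fam[j]].push_back(j);

  // --- residual e = y - eta, maintained incrementally --------------------
  NumericVector e(N);
  for (int j = 0; j < N; ++j) {
    double eta = mu + phi[fam[j]];
    for (int c = 0; c < C; ++c) eta += X(j, c) * cvec[c];
    eta += beta1 * (alpha[r[j]] * Dr[j] + alpha[s[j]] * Ds[j]);
    eta += beta2 * (gamma[r[j]] * GEr[j] + gamma[s[j]] * GEs[j]);
    e[j] = y[j] - eta;
  }

  const int n_keep = (iterations - burn_in + thin - 1) / thin;
  NumericMatrix cont(n_keep, 5 + C);   // mu beta1 beta2 s2phi s2eps covars...
  IntegerMatrix alpha_draws(n_keep, K), gamma_draws(n_keep, K);
  int kept = 0;

  RNGScope scope;

  for (int it = 0; it < iterations; ++it) {

    // mu ------------------------------------------------------------------
    if (include_mu) {
      double sum_e = 0.0;
      for (int j = 0; j < N; ++j) sum_e += e[j] + mu;
      double prec = N / s2eps + 1.0 / sigma2_beta;
      double mean = (sum_e / s2eps) / prec;
      double mu_new = R::rnorm(mean, std::sqrt(1.0 / prec));
      double d = mu_new - mu;
      for (int j = 0; j < N; ++j) e[j] -= d;
      mu = mu_new;
    }

    // covariate coefficients ----------------------------------------------
    for (int c = 0; c < C; ++c) {
      double sxx = 0.0, sxe = 0.0;
      for (int j = 0; j < N; ++j) {
        double x = X(j, c);
        sxx += x * x;
        sxe += x * (e[j] + cvec[c] * x);
      }
      double prec = sxx / s2eps + 1.0 / sigma2_beta;
      double mean = (sxe / s2eps) / prec;
      double cnew = R::rnorm(mean, std::sqrt(1.0 / prec));
      double d = cnew - cvec[c];
      for (int j = 0; j < N; ++j) e[j] -= d * X(j, c);
      cvec[c] = cnew;
    }

    if (!clamp_beta) {
      // beta1 ---------------------------------------------------------------
      {
        double sww = 0.0, swe = 0.0;
        for (int j = 0; j < N; ++j) {
          double w = alpha[r[j]] * Dr[j] + alpha[s[j]] * Ds[j];
          if (w != 0.0) { sww += w * w; swe += w * (e[j] + beta1 * w); }
        }
        double prec = sww / s2eps + 1.0 / sigma2_beta;
        double mean = (swe / s2eps) / prec;
        double bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double d = bnew - beta1;
        if (d != 0.0)
          for (int j = 0; j < N; ++j) {
            double w = alpha[r[j]] * Dr[j] + alpha[s[j]] * Ds[j];
            if (w != 0.0) e[j] -= d * w;
          }
        beta1 = bnew;
      }
      // beta2 ---------------------------------------------------------------
      {
        double svv = 0.0, sve = 0.0;
        for (int j = 0; j < N; ++j) {
          double v = gamma[r[j]] * GEr[j] + gamma[s[j]] * GEs[j];
          if (v != 0.0) { svv += v * v; sve += v * (e[j] + beta2 * v); }
        }
        double prec = svv / s2eps + 1.0 / sigma2_beta;
        double mean = (sve / s2eps) / prec;
        double bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double d = bnew - beta2;
        if (d != 0.0)
          for (int j = 0; j < N; ++j) {
            double v = gamma[r[j]] * GEr[j] + gamma[s[j]] * GEs[j];
            if (v != 0.0) e[j] -= d * v;
          }
        beta2 = bnew;
      }
    }

    // family effects phi_i and sigma2_phi ---------------------------------
    if (include_phi) {
      double ssphi = 0.0;
      for (int i = 0; i < M; ++i) {
        const std::vector<int>& jj = famIdx[i];
        double sum_e = 0.0;
        for (size_t u = 0; u < jj.size(); ++u) sum_e += e[jj[u]] + phi[i];
        double prec = jj.size() / s2eps + 1.0 / s2phi;
        double mean = (sum_e / s2eps) / prec;
        double pnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double d = pnew - phi[i];
        for (size_t u = 0; u < jj.size(); ++u) e[jj[u]] -= d;
        phi[i] = pnew;
        ssphi += pnew * pnew;
      }
      s2phi = rinvgamma(ig_a + 0.5 * M, ig_b + 0.5 * ssphi);
    }

    // sigma2_eps -----------------------------------------------------------
    if (fix_sigma2_eps > 0.0) {
      s2eps = fix_sigma2_eps;
    } else {
      double sse = 0.0;
      for (int j = 0; j < N; ++j) sse += e[j] * e[j];
      s2eps = rinvgamma(ig_a + 0.5 * N, ig_b + 0.5 * sse);
    }

    // spike indicators alpha_k (within-family) -----------------------------
    if (clamp_alpha < 0 && !clamp_beta) {
      for (int k = 1; k <= K; ++k) {
        int a = alpha[k];
        // delta log-likelihood of alpha_k = 1 vs 0 given residuals
        double dll = 0.0;
        const std::vector<int>& jr = idxR[k];
        const std::vector<int>& js = idxS[k];
        for (size_t u = 0; u < jr.size(); ++u) {
          int j = jr[u]; double d = beta1 * Dr[j];
          double e0 = e[j] + a * d;                 // residual if alpha_k = 0
          dll += (2.0 * e0 * d - d * d);
        }
        for (size_t u = 0; u < js.size(); ++u) {
          int j = js[u]; double d = beta1 * Ds[j];
          double e0 = e[j] + a * d;
          dll += (2.0 * e0 * d - d * d);
        }
        dll /= (2.0 * s2eps);
        double logit = std::log(p[k]) - std::log(1.0 - p[k]) + dll;
        int anew = (R::unif_rand() < 1.0 / (1.0 + std::exp(-logit))) ? 1 : 0;
        if (anew != a) {
          for (size_t u = 0; u < jr.size(); ++u) {
            int j = jr[u]; e[j] += (a - anew) * beta1 * Dr[j];
          }
          for (size_t u = 0; u < js.size(); ++u) {
            int j = js[u]; e[j] += (a - anew) * beta1 * Ds[j];
          }
          alpha[k] = anew;
        }
      }
    } else if (clamp_alpha < 0) {
      // no likelihood contribution (beta1 clamped at 0): prior draws
      for (int k = 1; k <= K; ++k)
        alpha[k] = (R::unif_rand() < p[k]) ? 1 : 0;
    }
    // hyperparameters p_k | alpha_k ~ Beta(1 + alpha_k, 2 - alpha_k)
    for (int k = 1; k <= K; ++k)
      p[k] = R::rbeta(1.0 + alpha[k], 2.0 - alpha[k]);

    // spike indicators gamma_k (between-family) ----------------------------
    if (clamp_gamma < 0 && !clamp_beta) {
      for (int k = 1; k <= K; ++k) {
        int g = gamma[k];
        double dll = 0.0;
        const std::vector<int>& jr = idxR[k];
        const std::vector<int>& js = idxS[k];
        for (size_t u = 0; u < jr.size(); ++u) {
          int j = jr[u]; double d = beta2 * GEr[j];
          double e0 = e[j] + g * d;
          dll += (2.0 * e0 * d - d * d);
        }
        for (size_t u = 0; u < js.size(); ++u) {
          int j = js[u]; double d = beta2 * GEs[j];
          double e0 = e[j] + g * d;
          dll += (2.0 * e0 * d - d * d);
        }
        dll /= (2.0 * s2eps);
        double logit = std::log(q[k]) - std::log(1.0 - q[k]) + dll;
        int gnew = (R::unif_rand() < 1.0 / (1.0 + std::exp(-logit))) ? 1 : 0;
        if (gnew != g) {
          for (size_t u = 0; u < jr.size(); ++u) {
            int j = jr[u]; e[j] += (g - gnew) * beta2 * GEr[j];
          }
          for (size_t u = 0; u < js.size(); ++u) {
            int j = js[u]; e[j] += (g - gnew) * beta2 * GEs[j];
          }
          gamma[k] = gnew;
        }
      }
    } else if (clamp_gamma < 0) {
      for (int k = 1; k <= K; ++k)
        gamma[k] = (R::unif_rand() < q[k]) ? 1 : 0;
    }
    for (int k = 1; k <= K; ++k)
      q[k] = R::rbeta(1.0 + gamma[k], 2.0 - gamma[k]);

    // record ---------------------------------------------------------------
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      cont(kept, 0) = mu;
      cont(kept, 1) = beta1;
      cont(kept, 2) = beta2;
      cont(kept, 3) = s2phi;
      cont(kept, 4) = s2eps;
      for (int c = 0; c < C; ++c) cont(kept, 5 + c) = cvec[c];
      for (int k = 0; k < K; ++k) {
        alpha_draws(kept, k) = alpha[k + 1];
        gamma_draws(kept, k) = gamma[k + 1];
      }
      ++kept;
    }
  }

  return List::create(_["cont"] = cont,
                      _["alpha"] = alpha_draws,
                      _["gamma"] = gamma_draws);
}
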