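// Adaptive Metropolis-within-Gibbs sampler for the zero-inflated binomial
// GLMM with multi-membership individual random intercepts:
//   y_d ~ ZIB(n_d, p_d, pi),  logit(p_d) = x_d' beta + u_{i(d)} + u_{j(d)}
//   u_k ~ Normal(0, sigma_u)
// Priors: Normal(0, sd_intercept) on the (raw-scale) intercept,
// Normal(0, sd_slope) on slopes, half-Cauchy(0, cauchy_scale) on sigma_u,
// Uniform(0, 1) on the zero-inflation probability pi.
// Covariates are centred internally for mixing; draws are returned on the
// raw scale. Uses R's RNG so set.seed() in R gives reproducible chains.
#include <Rcpp.h>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

static inline double logsumexp2(double a, double b) {
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// per-dyad ZIB log-likelihood; lpi = log(pi), l1mpi = log(1-pi)
static inline double ll_dyad(int y, int n, double lch, double eta,
                             double lpi, double l1mpi) {
  double sp = softplus(eta);          // log(1 + e^eta); log p = eta - sp
  if (y == 0) {
    return logsumexp2(lpi, l1mpi + n * (-sp));
  }
  return l1mpi + lch + y * (eta - sp) + (n - y) * (-sp);
}

// [[Rcpp::export(name = ".zib_mcmc_chain")]]
NumericMatrix zib_mcmc_chain(IntegerVector y, IntegerVector n,
                             NumericMatrix X, IntegerVector i1,
                             IntegerVector i2, int K, int iter, int warmup,
                             NumericVector init_beta, double init_ls,
                             double init_zt, double sd_intercept,
                             double sd_slope, double cauchy_scale,
                             IntegerVector cls, int idx_fNN, int idx_fSS) {
  const int D = y.size();
  const int P = X.ncol();

  // centre covariate columns (not the intercept column 0)
  NumericMatrix Xc(D, P);
  NumericVector cmean(P);
  for (int j = 0; j < P; ++j) {
    double m = 0.0;
    if (j > 0) {
      for (int d = 0; d < D; ++d) m += X(d, j);
      m /= D;
    }
    cmean[j] = m;
    for (int d = 0; d < D; ++d) Xc(d, j) = X(d, j) - m;
  }

  std::vector<double> lch(D);
  for (int d = 0; d < D; ++d) lch[d] = R::lchoose(n[d], y[d]);

  // adjacency: dyads touching individual k
  std::vector< std::vector<int> > dyads_of(K);
  for (int d = 0; d < D; ++d) {
    dyads_of[i1[d]].push_back(d);
    dyads_of[i2[d]].push_back(d);
  }

  std::vector<double> b(init_beta.begin(), init_beta.end());
  std::vector<double> u(K, 0.0);
  double ls = init_ls, zt = init_zt;
  double pi = 1.0 / (1.0 + std::exp(-zt));
  double lpi = std::log(pi), l1mpi = std::log1p(-pi);

  std::vector<double> eta(D), ll(D);
  for (int d = 0; d < D; ++d) {
    double e = 0.0;
    for (int j = 0; j < P; ++j) e += Xc(d, j) * b[j];
    e += u[i1[d]] + u[i2[d]];
    eta[d] = e;
    ll[d] = ll_dyad(y[d], n[d], lch[d], e, lpi, l1mpi);
  }
  double sumll = 0.0;
  for (int d = 0; d < D; ++d) sumll += ll[d];

  // priors as lambdas over current state
  auto beta_prior = [&](const std::vector<double>& bb) {
    double b0raw = bb[0];
    for (int j = 1; j < P; ++j) b0raw -= bb[j] * cmean[j];
    double lp = R::dnorm(b0raw, 0.0, sd_intercept, 1);
    for (int j = 1; j < P; ++j) lp += R::dnorm(bb[j], 0.0, sd_slope, 1);
    return lp;
  };
  auto sigma_prior = [&](double lsv) {
    double sg = std::exp(lsv);
    // half-Cauchy density + log-Jacobian of the log transform
    return std::log(2.0 / (M_PI * cauchy_scale *
                           (1.0 + (sg / cauchy_scale) * (sg / cauchy_scale)))) + lsv;
  };
  auto zt_prior = [&](double z) {  // Uniform(0,1) on pi, via logit Jacobian
    return -softplus(z) - softplus(-z);
  };
  auto u_prior_all = [&](double sg) {
    double lp = 0.0;
    for (int k = 0; k < K; ++k) lp += R::dnorm(u[k], 0.0, sg, 1);
    return lp;
  };

  std::vector<double> lstep_b(P, std::log(0.05));
  // joint adaptive-Metropolis state for the fixed-effect block
  std::vector<double> am_mean(P, 0.0);
  std::vector<double> am_M2(P * P, 0.0);
  long am_n = 0;
  std::vector<double> am_L(P * P, 0.0);   // Cholesky of proposal covariance
  bool am_ok = false;
  double lstep_joint = std::log(1.0);
  std::vector<double> lstep_u(K, std::log(0.3));
  double lstep_ls = std::log(0.3), lstep_zt = std::log(0.3);
  double lstep_tr = std::log(0.2);
  double lstep_cl0 = std::log(0.2), lstep_cl1 = std::log(0.2);
  const double target = 0.44;

  const int keep = iter - warmup;
  const int ncol_out = P + 2 + K + 2;  // beta, sigma, pi, u, r2, lp
  NumericMatrix out(keep, ncol_out);

  std::vector<double> ll_new(D), eta_new(D);
  RNGScope scope;

  for (int t = 0; t < iter; ++t) {
    double gam = std::pow(t + 1.0, -0.6);

    // --- fixed effects, coordinate-wise random walk ---
    for (int j = 0; j < P; ++j) {
      double db = R::norm_rand() * std::exp(lstep_b[j]);
      double bj_new = b[j] + db;
      double sumll_new = 0.0;
      for (int d = 0; d < D; ++d) {
        double e = eta[d] + Xc(d, j) * db;
        eta_new[d] = e;
        ll_new[d] = ll_dyad(y[d], n[d], lch[d], e, lpi, l1mpi);
        sumll_new += ll_new[d];
      }
      std::vector<double> bb = b; bb[j] = bj_new;
      double lacc = (sumll_new + beta_prior(bb)) - (sumll + beta_prior(b));
      double alpha = std::min(1.0, std::exp(lacc));
      if (R::unif_rand() < alpha) {
        b[j] = bj_new;
        std::swap(eta, eta_new);
        std::swap(ll, ll_new);
        sumll = sumll_new;
      }
      if (t < warmup) lstep_b[j] += gam * (alpha - target);
    }

    // --- fixed effects, joint adaptive-Metropolis update ---
    if (am_n >= 10 * P && (t % 25 == 0) && t < warmup) {
      // refresh Cholesky of 2.38^2/P * cov (+ jitter) from the running moments
      std::vector<double> C(P * P);
      double sc = 5.6644 / P;  // 2.38^2 / P
      for (int a = 0; a < P; ++a)
        for (int c = 0; c < P; ++c)
          C[a * P + c] = sc * am_M2[a * P + c] / (am_n - 1);
      for (int a = 0; a < P; ++a) C[a * P + a] += 1e-10;
      am_ok = true;
      for (int a = 0; a < P && am_ok; ++a) {       // lower-triangular Cholesky
        for (int c = 0; c <= a; ++c) {
          double sum = C[a * P + c];
          for (int k2 = 0; k2 < c; ++k2) sum -= am_L[a * P + k2] * am_L[c * P + k2];
          if (a == c) {
            if (sum <= 0) { am_ok = false; break; }
            am_L[a * P + a] = std::sqrt(sum);
          } else {
            am_L[a * P + c] = sum / am_L[c * P + c];
          }
        }
      }
    }
    for (int rep = 0; am_ok && rep < 5; ++rep) {
      std::vector<double> z(P), db(P, 0.0);
      for (int j = 0; j < P; ++j) z[j] = R::norm_rand();
      double step = std::exp(lstep_joint);
      for (int a = 0; a < P; ++a)
        for (int c = 0; c <= a; ++c) db[a] += step * am_L[a * P + c] * z[c];
      std::vector<double> bb(P);
      for (int j = 0; j < P; ++j) bb[j] = b[j] + db[j];
      double sumll_new = 0.0;
      for (int d = 0; d < D; ++d) {
        double e = eta[d];
        for (int j = 0; j < P; ++j) e += Xc(d, j) * db[j];
        eta_new[d] = e;
        ll_new[d] = ll_dyad(y[d], n[d], lch[d], e, lpi, l1mpi);
        sumll_new += ll_new[d];
      }
      double lacc = (sumll_new + beta_prior(bb)) - (sumll + beta_prior(b));
      double alpha = std::min(1.0, std::exp(lacc));
      if (R::unif_rand() < alpha) {
        b = bb;
        std::swap(eta, eta_new);
        std::swap(ll, ll_new);
        sumll = sumll_new;
      }
      if (t < warmup) lstep_joint += gam * (alpha - 0.23);
    }
    // accumulate running moments of beta during warmup (Welford)
    if (t < warmup) {
      ++am_n;
      std::vector<double> delta(P);
      for (int j = 0; j < P; ++j) {
        delta[j] = b[j] - am_mean[j];
        am_mean[j] += delta[j] / am_n;
      }
      for (int a = 0; a < P; ++a)
        for (int c = 0; c < P; ++c)
          am_M2[a * P + c] += delta[a] * (b[c] - am_mean[c]);
    }

    // --- random effects, single-site ---
    double sg = std::exp(ls);
    for (int k = 0; k < K; ++k) {
      double du = R::norm_rand() * std::exp(lstep_u[k]);
      double uk_new = u[k] + du;
      double dll = 0.0;
      const std::vector<int>& dk = dyads_of[k];
      for (size_t a = 0; a < dk.size(); ++a) {
        int d = dk[a];
        double lnew = ll_dyad(y[d], n[d], lch[d], eta[d] + du, lpi, l1mpi);
        dll += lnew - ll[d];
      }
      double lacc = dll + R::dnorm(uk_new, 0.0, sg, 1) - R::dnorm(u[k], 0.0, sg, 1);
      double alpha = std::min(1.0, std::exp(lacc));
      if (R::unif_rand() < alpha) {
        u[k] = uk_new;
        for (size_t a = 0; a < dk.size(); ++a) {
          int d = dk[a];
          eta[d] += du;
          ll[d] = ll_dyad(y[d], n[d], lch[d], eta[d], lpi, l1mpi);
        }
        sumll += dll;
      }
      if (t < warmup) lstep_u[k] += gam * (alpha - target);
    }

    // --- translation sweep along the likelihood-flat direction ---
    // b0 -> b0 + delta, all u_k -> u_k - delta/2 leaves every eta unchanged,
    // so only the priors enter; this decorrelates the intercept from the
    // random-effect mean, the slowest direction under single-site updates.
    {
      double delta = R::norm_rand() * std::exp(lstep_tr);
      double sg2 = std::exp(ls);
      double dlp = 0.0;
      for (int k = 0; k < K; ++k)
        dlp += R::dnorm(u[k] - delta / 2.0, 0.0, sg2, 1) -
               R::dnorm(u[k], 0.0, sg2, 1);
      std::vector<double> bb = b; bb[0] += delta;
      dlp += beta_prior(bb) - beta_prior(b);
      double alpha = std::min(1.0, std::exp(dlp));
      if (R::unif_rand() < alpha) {
        b[0] += delta;
        for (int k = 0; k < K; ++k) u[k] -= delta / 2.0;
      }
      if (t < warmup) lstep_tr += gam * (alpha - target);
    }

    // --- class translations: shift one foraging class's random intercepts
    // with compensating fixed-effect shifts; every eta is unchanged, so only
    // priors enter. Shifting sponger u's by a pairs with
    // (intercept, fNN, fSS) += (-a, a, -a); shifting non-sponger u's by b
    // pairs with (+)(-b, -b, b). These are the remaining likelihood-flat
    // directions coupling the dummies to class-mean random effects.
    if (idx_fNN >= 0 && idx_fSS >= 0) {
      for (int which = 0; which < 2; ++which) {
        double& lstep_cl = which ? lstep_cl1 : lstep_cl0;
        double a = R::norm_rand() * std::exp(lstep_cl);
        double sgc = std::exp(ls);
        double dlp = 0.0;
        for (int k = 0; k < K; ++k) {
          if (cls[k] == which) {
            dlp += R::dnorm(u[k] + a, 0.0, sgc, 1) - R::dnorm(u[k], 0.0, sgc, 1);
          }
        }
        // columns are centred, so the intercept compensation picks up the
        // dummy column means (eta uses fNN - mean(fNN), etc.)
        std::vector<double> bb = b;
        double mN = cmean[idx_fNN], mS = cmean[idx_fSS];
        if (which == 1) {        // spongers shifted
          bb[0] -= a * (1.0 - mN + mS); bb[idx_fNN] += a; bb[idx_fSS] -= a;
        } else {                 // non-spongers shifted
          bb[0] -= a * (1.0 + mN - mS); bb[idx_fNN] -= a; bb[idx_fSS] += a;
        }
        dlp += beta_prior(bb) - beta_prior(b);
        double alpha = std::min(1.0, std::exp(dlp));
        if (R::unif_rand() < alpha) {
          b = bb;
          for (int k = 0; k < K; ++k) if (cls[k] == which) u[k] += a;
        }
        if (t < warmup) lstep_cl += gam * (alpha - target);
      }
    }

    // --- sigma_u (log scale) ---
    {
      double ls_new = ls + R::norm_rand() * std::exp(lstep_ls);
      double lacc = (sigma_prior(ls_new) + u_prior_all(std::exp(ls_new))) -
                    (sigma_prior(ls) + u_prior_all(std::exp(ls)));
      double alpha = std::min(1.0, std::exp(lacc));
      if (R::unif_rand() < alpha) ls = ls_new;
      if (t < warmup) lstep_ls += gam * (alpha - target);
    }

    // --- zero-inflation (logit scale) ---
    {
      double zt_new = zt + R::norm_rand() * std::exp(lstep_zt);
      double pi_new = 1.0 / (1.0 + std::exp(-zt_new));
      double lpi_n = std::log(pi_new), l1mpi_n = std::log1p(-pi_new);
      double sumll_new = 0.0;
      for (int d = 0; d < D; ++d) {
        ll_new[d] = ll_dyad(y[d], n[d], lch[d], eta[d], lpi_n, l1mpi_n);
        sumll_new += ll_new[d];
      }
      double lacc = (sumll_new + zt_prior(zt_new)) - (sumll + zt_prior(zt));
      double alpha = std::min(1.0, std::exp(lacc));
      if (R::unif_rand() < alpha) {
        zt = zt_new; pi = pi_new; lpi = lpi_n; l1mpi = l1mpi_n;
        std::swap(ll, ll_new);
        sumll = sumll_new;
      }
      if (t < warmup) lstep_zt += gam * (alpha - target);
    }

    // --- store ---
    if (t >= warmup) {
      int r = t - warmup;
      double b0raw = b[0];
      for (int j = 1; j < P; ++j) b0raw -= b[j] * cmean[j];
      out(r, 0) = b0raw;
      for (int j = 1; j < P; ++j) out(r, j) = b[j];
      out(r, P) = std::exp(ls);
      out(r, P + 1) = pi;
      for (int k = 0; k < K; ++k) out(r, P + 2 + k) = u[k];
      // Bayesian R2 ingredients for this draw: fitted mean proportion
      double m_mu = 0.0, m_re = 0.0;
      std::vector<double> mu(D);
      for (int d = 0; d < D; ++d) {
        double p = 1.0 / (1.0 + std::exp(-eta[d]));
        mu[d] = (1.0 - pi) * p;
        m_mu += mu[d];
        m_re += (double)y[d] / n[d] - mu[d];
      }
      m_mu /= D; m_re /= D;
      double v_mu = 0.0, v_re = 0.0;
      for (int d = 0; d < D; ++d) {
        double rmu = mu[d] - m_mu;
        double rre = ((double)y[d] / n[d] - mu[d]) - m_re;
        v_mu += rmu * rmu;
        v_re += rre * rre;
      }
      v_mu /= (D - 1); v_re /= (D - 1);
      out(r, P + 2 + K) = v_mu / (v_mu + v_re);
      out(r, P + 2 + K + 1) = sumll + beta_prior(b) + sigma_prior(ls) +
        u_prior_all(std::exp(ls)) + zt_prior(zt);
    }
  }
  return out;
}
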