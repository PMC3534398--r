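// Gibbs samplers for whole-genome marker regression on de-regressed proofs:
//  - Bayesian LASSO (double-exponential prior on marker effects, Park-Casella
//    conditional hierarchy) with an optional pedigree polygenic effect and an
//    optional within-chain permutation schedule for null-effect sampling.
//  - Bayes C-pi mixture sampler (point mass at zero, common slab variance,
//    uniform prior on the null proportion pi).
// All randomness goes through R's RNG so set.seed() on the R side gives
// bit-identical chains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Inverse-Gaussian draw, Michael/Schucany/Haas.  mu, shape > 0.
static double rinvgauss(double mu, double shape) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + 0.5 * mu * mu * y / shape -
    0.5 * (mu / shape) * std::sqrt(4.0 * mu * shape * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Scaled-inverse-chi-square draw: (nu * s2 + ss) / chisq(nu + df_data)
static double rscinv(double nu, double s2, double ss, double df_data) {
  double df = nu + df_data;
  return (nu * s2 + ss) / Rf_rchisq(df);
}

// Fisher-Yates permutation of 0..n-1 using R's RNG.
static arma::uvec rperm(int n) {
  arma::uvec p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// Polygenic update in the eigenbasis of A (A = U diag(d) U').  With one
// record per animal the full conditional of gamma (S = U gamma) has a
// diagonal precision I/s2e + D^-1/s2s, so the joint draw is elementwise.
static void update_polygenic(const arma::mat& U, const arma::vec& d,
                             arma::vec& gamma, arma::vec& S, arma::vec& resid,
                             double sigma2e, double sigma2s, double dtol) {
  arma::vec t = U.t() * (resid + S);
  int n = (int)gamma.n_elem;
  for (int k = 0; k < n; ++k) {
    if (d[k] <= dtol) { gamma[k] = 0.0; continue; }
    double v = 1.0 / (1.0 / sigma2e + 1.0 / (d[k] * sigma2s));
    gamma[k] = v * t[k] / sigma2e + std::sqrt(v) * norm_rand();
  }
  arma::vec Snew = U * gamma;
  resid += S - Snew;
  S = Snew;
}

// [[Rcpp::export(name = ".blasso_gibbs_cpp")]]
List blasso_gibbs_cpp(const arma::vec& y0, const arma::mat& X,
                      bool use_poly, const arma::mat& U0, const arma::vec& d,
                      int niter, int burnin, int thin,
                      double lambda, bool sample_lambda,
                      double lambda_shape, double lambda_rate,
                      double nu_e, double scale_e,
                      bool fix_sigma2e, double sigma2e_init,
                      double nu_s, double scale_s,
                      bool fix_mu, int perm_h) {
  RNGScope scope;
  const int n = (int)y0.n_elem;
  const int p = (int)X.n_cols;
  const double dtol = 1e-10;

  arma::vec y = y0;                 // working (possibly permuted) response
  arma::mat U = use_poly ? U0 : arma::mat();
  arma::vec cj(p);                  // x_j'x_j, invariant under permutation
  for (int j = 0; j < p; ++j) cj[j] = arma::dot(X.col(j), X.col(j));

  double mu = fix_mu ? 0.0 : arma::mean(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec tau2(p, arma::fill::ones);
  arma::vec gamma(use_poly ? n : 0, arma::fill::zeros);
  arma::vec S(n, arma::fill::zeros);
  double vy = arma::var(y);
  if (!std::isfinite(vy) || vy <= 0) vy = 1e-8;
  double sigma2e = fix_sigma2e ? sigma2e_init : std::max(vy * 0.5, 1e-8);
  double sigma2s = std::max(vy * 0.25, 1e-8);
  double lambda2 = lambda * lambda;

  arma::vec resid = y - mu - S;     // beta starts at zero
  // Xbeta is recovered as y - mu - S - resid when a reshuffle needs it.

  const int nstore = (niter - burnin) / thin;
  arma::mat beta_store(p, std::max(nstore, 0));
  arma::vec mu_store(std::max(nstore, 0)), s2e_store(std::max(nstore, 0)),
            s2s_store(std::max(nstore, 0)), lam_store(std::max(nstore, 0));
  int nq = 0;                        // eigenvalues above tolerance
  if (use_poly) for (int k = 0; k < n; ++k) if (d[k] > dtol) ++nq;

  int stored = 0;
  for (int iter = 1; iter <= niter; ++iter) {
    // within-chain permutation: reshuffle the response (and its polygenic
    // index) against the genotype rows every perm_h iterations
    if (perm_h > 0 && iter % perm_h == 0) {
      arma::vec xb = y - mu - S - resid;
      arma::uvec pm = rperm(n);
      y = y0.elem(pm);
      if (use_poly) {
        U = U0.rows(pm);
        S = U * gamma;
      }
      resid = y - mu - S - xb;
    }

    if (!fix_mu) {
      double mu_new = mu + arma::mean(resid) +
        std::sqrt(sigma2e / n) * norm_rand();
      resid += mu - mu_new;
      mu = mu_new;
    }

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (cj[j] <= 0) { beta[j] = 0.0; continue; }
      const double* xj = X.colptr(j);
      double bold = beta[j];
      double rhs = 0.0;
      const double* r = resid.memptr();
      for (int i = 0; i < n; ++i) rhs += xj[i] * r[i];
      rhs += cj[j] * bold;
      double prec = cj[j] + 1.0 / tau2[j];
      double bnew = rhs / prec + std::sqrt(sigma2e / prec) * norm_rand();
      double dlt = bold - bnew;
      double* rw = resid.memptr();
      for (int i = 0; i < n; ++i) rw[i] += xj[i] * dlt;
      beta[j] = bnew;
      // latent scale: 1/tau2 | beta ~ InvGauss(sqrt(lambda2 s2e / b^2), lambda2)
      double b2 = bnew * bnew;
      double mup = std::sqrt(lambda2 * sigma2e / std::max(b2, 1e-300));
      if (mup > 1e8) mup = 1e8;
      double itau = rinvgauss(mup, lambda2);
      tau2[j] = 1.0 / std::max(itau, 1e-12);
    }

    if (sample_lambda) {
      // gamma prior on lambda^2: full conditional Gamma(shape + p, rate + sum tau2/2)
      double rt = lambda_rate + 0.5 * arma::accu(tau2);
      lambda2 = Rf_rgamma(lambda_shape + p, 1.0 / rt);
      if (lambda2 < 1e-12) lambda2 = 1e-12;
    }

    if (use_poly) {
      update_polygenic(U, d, gamma, S, resid, sigma2e, sigma2s, dtol);
      double ssq = 0.0;
      for (int k = 0; k < n; ++k)
        if (d[k] > dtol) ssq += gamma[k] * gamma[k] / d[k];
      sigma2s = rscinv(nu_s, scale_s, ssq, (double)nq);
      if (sigma2s < 1e-12) sigma2s = 1e-12;
    }

    if (!fix_sigma2e) {
      // beta prior scales with sigma2e, so the sum of squares includes
      // beta' D_tau^-1 beta and the degrees of freedom include p
      double ss = arma::dot(resid, resid);
      for (int j = 0; j < p; ++j) ss += beta[j] * beta[j] / tau2[j];
      sigma2e = rscinv(nu_e, scale_e, ss, (double)(n + p));
      if (sigma2e < 1e-12) sigma2e = 1e-12;
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && stored < nstore) {
      beta_store.col(stored) = beta;
      mu_store[stored] = mu;
      s2e_store[stored] = sigma2e;
      s2s_store[stored] = use_poly ? sigma2s : NA_REAL;
      lam_store[stored] = std::sqrt(lambda2);
      ++stored;
    }
  }

  return List::create(_["beta"] = beta_store, _["mu"] = mu_store,
                      _["sigma2e"] = s2e_store, _["sigma2s"] = s2s_store,
                      _["lambda"] = lam_store, _["nstore"] = stored);
}

// [[Rcpp::export(name = ".bayescpi_gibbs_cpp")]]
List bayescpi_gibbs_cpp(const arma::vec& y0, const arma::mat& X,
                        bool use_poly, const arma::mat& U0, const arma::vec& d,
                        int niter, int burnin, int thin,
                        double nu_b, double scale_b,
                        double nu_e, double scale_e,
                        double nu_s, double scale_s,
                        double pi_init, bool store_beta) {
  RNGScope scope;
  const int n = (int)y0.n_elem;
  const int p = (int)X.n_cols;
  const double dtol = 1e-10;

  arma::vec y = y0;
  arma::vec cj(p);
  for (int j = 0; j < p; ++j) cj[j] = arma::dot(X.col(j), X.col(j));

  double mu = arma::mean(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::zeros);
  arma::vec gamma(use_poly ? n : 0, arma::fill::zeros);
  arma::vec S(n, arma::fill::zeros);
  double vy = arma::var(y);
  if (!std::isfinite(vy) || vy <= 0) vy = 1e-8;
  double sigma2e = std::max(vy * 0.5, 1e-8);
  double sigma2s = std::max(vy * 0.25, 1e-8);
  double sigma2b = std::max(scale_b, 1e-10);
  double pi = pi_init;

  arma::vec resid = y - mu - S;
  int nq = 0;
  if (use_poly) for (int k = 0; k < n; ++k) if (d[k] > dtol) ++nq;

  const int nstore = (niter - burnin) / thin;
  arma::vec pi_store(std::max(nstore, 0)), s2b_store(std::max(nstore, 0)),
            s2e_store(std::max(nstore, 0)), s2s_store(std::max(nstore, 0)),
            mu_store(std::max(nstore, 0));
  arma::vec incl_sum(p, arma::fill::zeros), beta_sum(p, arma::fill::zeros);
  arma::mat beta_store(store_beta ? p : 0, store_beta ? std::max(nstore, 0) : 0);

  int stored = 0;
  for (int iter = 1; iter <= niter; ++iter) {
    double mu_new = mu + arma::mean(resid) + std::sqrt(sigma2e / n) * norm_rand();
    resid += mu - mu_new;
    mu = mu_new;

    int m = 0;                      // included markers this round
    double ssb = 0.0;
    for (int j = 0; j < p; ++j) {
      if (cj[j] <= 0) { beta[j] = 0.0; delta[j] = 0; continue; }
      const double* xj = X.colptr(j);
      double bold = beta[j];
      double rhs = 0.0;
      const double* r = resid.memptr();
      for (int i = 0; i < n; ++i) rhs += xj[i] * r[i];
      rhs += cj[j] * bold;
      // marginal likelihood ratio (b_j integrated out) for delta_j = 1 vs 0
      double den = cj[j] * sigma2b + sigma2e;
      double logLR = 0.5 * std::log(sigma2e / den) +
        0.5 * rhs * rhs * sigma2b / (sigma2e * den);
      double logit = std::log1p(-pi) - std::log(pi) + logLR; // log odds incl.
      double p1 = 1.0 / (1.0 + std::exp(-logit));
      double bnew = 0.0;
      if (unif_rand() < p1) {
        double prec = cj[j] + sigma2e / sigma2b;
        bnew = rhs / prec + std::sqrt(sigma2e / prec) * norm_rand();
        delta[j] = 1;
        ++m;
        ssb += bnew * bnew;
      } else {
        delta[j] = 0;
      }
      if (bnew != bold) {
        double dlt = bold - bnew;
        double* rw = resid.memptr();
        for (int i = 0; i < n; ++i) rw[i] += xj[i] * dlt;
      }
      beta[j] = bnew;
    }

    sigma2b = rscinv(nu_b, scale_b, ssb, (double)m);
    if (sigma2b < 1e-12) sigma2b = 1e-12;
    // uniform prior on pi (proportion of null markers)
    pi = Rf_rbeta((double)(p - m) + 1.0, (double)m + 1.0);

    if (use_poly) {
      update_polygenic(U0, d, gamma, S, resid, sigma2e, sigma2s, dtol);
      double ssq = 0.0;
      for (int k = 0; k < n; ++k)
        if (d[k] > dtol) ssq += gamma[k] * gamma[k] / d[k];
      sigma2s = rscinv(nu_s, scale_s, ssq, (double)nq);
      if (sigma2s < 1e-12) sigma2s = 1e-12;
    }

    double ss = arma::dot(resid, resid);
    sigma2e = rscinv(nu_e, scale_e, ss, (double)n);
    if (sigma2e < 1e-12) sigma2e = 1e-12;

    if (iter > burnin && (iter - burnin) % thin == 0 && stored < nstore) {
      pi_store[stored] = pi;
      s2b_store[stored] = sigma2b;
      s2e_store[stored] = sigma2e;
      s2s_store[stored] = use_poly ? sigma2s : NA_REAL;
      mu_store[stored] = mu;
      for (int j = 0; j < p; ++j) {
        incl_sum[j] += delta[j];
        beta_sum[j] += beta[j];
      }
      if (store_beta) beta_store.col(stored) = beta;
      ++stored;
    }
  }

  arma::vec incl = incl_sum / std::max(stored, 1);
  arma::vec bmean = beta_sum / std::max(stored, 1);
  return List::create(_["pi"] = pi_store, _["sigma2b"] = s2b_store,
                      _["sigma2e"] = s2e_store, _["sigma2s"] = s2s_store,
                      _["mu"] = mu_store, _["inclusion"] = incl,
                      _["beta_mean"] = bmean, _["beta"] = beta_store,
                      _["nstore"] = stored);
}
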