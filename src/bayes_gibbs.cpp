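#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for whole-genome regression under the Bayes
// alphabet. Model: y = W b + sum_j x_j alpha_j delta_j + e,
// e ~ N(0, sigma2_e I); flat priors on b; delta_j ~ Bern(1 - pi);
// alpha_j | delta_j = 1 ~ N(0, sigma2_j) with
//   method 0 (BayesB):   per-marker sigma2_j ~ scaled-inv-chi2(nu_a, s2_a)
//   method 1 (BayesC):   one shared sigma2_alpha, pi fixed
//   method 2 (BayesCpi): as BayesC, pi ~ Beta(#excluded+1, #included+1)
//   method 3 (BayesC0):  all markers in (pi = 0), shared sigma2_alpha
// sigma2_e ~ scaled-inv-chi2(nu_e, s2_e). Residual-update scheme: the
// working residual e always excludes no marker; a marker's own
// contribution is removed before its full conditional is formed.
// Uses R's RNG, so draws are reproducible under set.seed().

static inline double rinvchisq(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(const NumericMatrix& X, const NumericVector& y,
                     const NumericMatrix& W, int method, double pi0,
                     int n_iter, int n_burnin, int thin,
                     double nu_a, double s2_a, double nu_e, double s2_e) {
  const int n = X.nrow(), m = X.ncol(), q = W.ncol();
  const double* Xp = X.begin();
  const double* Wp = W.begin();
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter");
  const int n_keep = (n_iter - n_burnin) / thin;
  if (n_keep < 1) stop("no retained draws with this n_iter/n_burnin/thin");

  std::vector<double> xpx(m), wpw(q);
  for (int j = 0; j < m; ++j) {
    const double* xj = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xpx[j] = s;
  }
  for (int k = 0; k < q; ++k) {
    const double* wk = Wp + (size_t)k * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wk[i] * wk[i];
    if (s <= 0.0) stop("fixed-effect design column with zero sum of squares");
    wpw[k] = s;
  }

  std::vector<double> b(q, 0.0), alpha(m, 0.0), e(n);
  std::vector<int> delta(m, 0);
  std::vector<double> varj(m, s2_a);  // per-marker variance (BayesB)
  double sigma2_e = s2_e > 0 ? s2_e : 1.0;
  double sigma2_a_common = s2_a;
  double pi = (method == 3) ? 0.0 : pi0;
  for (int i = 0; i < n; ++i) e[i] = y[i];

  NumericMatrix effects(n_keep, m), fixed(n_keep, q);
  IntegerMatrix incl(n_keep, m);
  NumericVector s2e_chain(n_keep), s2a_chain(n_keep), pi_chain(n_keep);

  int keep = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects, single site, flat prior
    for (int k = 0; k < q; ++k) {
      const double* wk = Wp + (size_t)k * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += wk[i] * e[i];
      rhs += wpw[k] * b[k];
      double mean = rhs / wpw[k];
      double bnew = R::rnorm(mean, std::sqrt(sigma2_e / wpw[k]));
      double diff = b[k] - bnew;
      for (int i = 0; i < n; ++i) e[i] += wk[i] * diff;
      b[k] = bnew;
    }

    for (int j = 0; j < m; ++j) {
      if (xpx[j] <= 0.0) { delta[j] = 0; alpha[j] = 0.0; continue; }
      const double* xj = Xp + (size_t)j * n;
      // remove this marker's contribution
      if (alpha[j] != 0.0) {
        double aj = alpha[j];
        for (int i = 0; i < n; ++i) e[i] += xj[i] * aj;
        alpha[j] = 0.0;
      }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      double vj = (method == 0) ? varj[j] : sigma2_a_common;
      const double c = xpx[j];
      bool include;
      if (method == 3) {
        include = true;
      } else if (pi >= 1.0) {
        include = false;
      } else if (pi <= 0.0) {
        include = true;
      } else {
        // marginal of rhs: N(0, c*sigma2_e) vs N(0, c^2*vj + c*sigma2_e)
        double v0 = c * sigma2_e;
        double v1 = c * c * vj + c * sigma2_e;
        double log_bf = 0.5 * (std::log(v0) - std::log(v1) +
                               rhs * rhs * (1.0 / v0 - 1.0 / v1));
        double r = std::log((1.0 - pi) / pi) + log_bf;
        double p_incl = 1.0 / (1.0 + std::exp(-r));
        include = R::unif_rand() < p_incl;
      }
      if (include) {
        double lhs = c + sigma2_e / vj;
        double mean = rhs / lhs;
        double aj = R::rnorm(mean, std::sqrt(sigma2_e / lhs));
        alpha[j] = aj;
        delta[j] = 1;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * aj;
      } else {
        delta[j] = 0;
      }
      if (method == 0) {
        // per-marker variance: posterior when included, prior draw otherwise
        if (delta[j] == 1) {
          varj[j] = rinvchisq(nu_a + 1.0,
                              (nu_a * s2_a + alpha[j] * alpha[j]) / (nu_a + 1.0));
        } else {
          varj[j] = rinvchisq(nu_a, s2_a);
        }
      }
    }

    if (method == 1 || method == 2 || method == 3) {
      double ss = 0.0;
      int cnt = 0;
      for (int j = 0; j < m; ++j) {
        if (delta[j] == 1) { ss += alpha[j] * alpha[j]; ++cnt; }
      }
      sigma2_a_common = rinvchisq(nu_a + cnt, (nu_a * s2_a + ss) / (nu_a + cnt));
    }
    if (method == 2) {
      int m_in = 0;
      for (int j = 0; j < m; ++j) m_in += delta[j];
      pi = R::rbeta((double)(m - m_in) + 1.0, (double)m_in + 1.0);
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = (sse + nu_e * s2_e) / R::rchisq((double)n + nu_e);
    if (!std::isfinite(sigma2_e) || sigma2_e > 1e12 * (s2_e > 0 ? s2_e : 1.0)) {
      stop("residual variance diverged at iteration %d (sigma2_e = %g)",
           iter, sigma2_e);
    }

    if (iter > n_burnin && (iter - n_burnin) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        effects(keep, j) = alpha[j];
        incl(keep, j) = delta[j];
      }
      for (int k = 0; k < q; ++k) fixed(keep, k) = b[k];
      s2e_chain[keep] = sigma2_e;
      s2a_chain[keep] = sigma2_a_common;
      pi_chain[keep] = pi;
      ++keep;
    }
  }

  return List::create(
    _["effects"] = effects, _["indicators"] = incl, _["fixed"] = fixed,
    _["sigma2_e"] = s2e_chain, _["sigma2_alpha"] = s2a_chain,
    _["pi"] = pi_chain, _["n_kept"] = keep);
}
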