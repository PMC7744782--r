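#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-gene negative-binomial GLM (log link, known dispersion) fitted by
// IRLS; returns the Wald estimate and standard error of one coefficient.
// counts: genes x samples; X: samples x p design; offs: log size factors;
// alpha: per-gene NB dispersion (var = mu + alpha mu^2); ci: 0-based index
// of the tested coefficient.
// [[Rcpp::export(name = ".nb_wald_cpp")]]
NumericMatrix nb_wald_cpp(NumericMatrix counts, NumericMatrix Xr,
                          NumericVector offs, NumericVector alpha, int ci) {
  const int G = counts.nrow(), n = counts.ncol();
  arma::mat X(Xr.begin(), n, Xr.ncol(), false);
  const int p = X.n_cols;
  arma::vec o(offs.begin(), n, false);
  NumericMatrix res(G, 2);

  arma::vec y(n), eta(n), mu(n), w(n), z(n), beta(p), beta_old(p);
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < n; ++j) y(j) = counts(g, j);
    const double a = alpha[g];
    // initial linear predictor from shifted log counts
    for (int j = 0; j < n; ++j) eta(j) = std::log(y(j) + 0.5) - o(j);
    beta.zeros();
    bool ok = true;
    arma::mat XtWX(p, p);
    // one unweighted LS step for starting values
    ok = arma::solve(beta, X.t() * X, X.t() * eta, arma::solve_opts::no_approx);
    for (int it = 0; ok && it < 50; ++it) {
      beta_old = beta;
      eta = X * beta + o;
      for (int j = 0; j < n; ++j) {
        double e = eta(j);
        if (e > 30.0) e = 30.0;
        if (e < -30.0) e = -30.0;
        mu(j) = std::exp(e);
        w(j) = mu(j) / (1.0 + a * mu(j));
        z(j) = (eta(j) > 30.0 ? 30.0 : (eta(j) < -30.0 ? -30.0 : eta(j))) - o(j)
             + (y(j) - mu(j)) / mu(j);
      }
      arma::mat Xw = X.each_col() % w;
      XtWX = X.t() * Xw;
      ok = arma::solve(beta, XtWX, Xw.t() * z, arma::solve_opts::no_approx);
      if (!ok) break;
      if (arma::norm(beta - beta_old, "inf") < 1e-10) break;
    }
    if (!ok) { res(g, 0) = NA_REAL; res(g, 1) = NA_REAL; continue; }
    arma::mat cov;
    bool inv = arma::inv_sympd(cov, XtWX);
    if (!inv) inv = arma::inv(cov, XtWX);
    if (!inv || cov(ci, ci) <= 0.0 || !std::isfinite(cov(ci, ci))) {
      res(g, 0) = NA_REAL; res(g, 1) = NA_REAL; continue;
    }
    res(g, 0) = beta(ci);
    res(g, 1) = std::sqrt(cov(ci, ci));
  }
  return res;
}
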