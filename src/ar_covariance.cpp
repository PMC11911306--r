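#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Covariance-method (non-windowed least-squares) AR coefficient estimation.
// Minimises sum_{t=p}^{n-1} (x[t] - sum_k phi_k x[t-k])^2 over phi.
// The (p+1)x(p+1) cross-product matrix c(i,j) = sum_{t=p}^{n-1} x[t-i]*x[t-j]
// is filled from its first row by the shift recursion
//   c(i+1,j+1) = c(i,j) + x[p-1-i]*x[p-1-j] - x[n-1-i]*x[n-1-j],
// which keeps the cost at O(n*p + p^2) instead of O(n*p^2).
// [[Rcpp::export]]
Rcpp::List ar_covariance_fit_cpp(const arma::vec& x, const int order) {
  const int n = x.n_elem;
  const int p = order;
  if (n <= 2 * p)
    Rcpp::stop("signal length must exceed twice the model order");

  arma::mat C(p + 1, p + 1, arma::fill::zeros);
  for (int j = 0; j <= p; ++j) {
    double s = 0.0;
    for (int t = p; t < n; ++t) s += x[t] * x[t - j];
    C(0, j) = s;
    C(j, 0) = s;
  }
  for (int i = 0; i < p; ++i) {
    for (int j = i; j < p; ++j) {
      const double v = C(i, j) + x[p - 1 - i] * x[p - 1 - j]
                               - x[n - 1 - i] * x[n - 1 - j];
      C(i + 1, j + 1) = v;
      C(j + 1, i + 1) = v;
    }
  }

  arma::mat R = C.submat(1, 1, p, p);
  arma::vec r = C.submat(1, 0, p, 0);
  const double rc = arma::rcond(R);
  if (!std::isfinite(rc) || rc < 1e-14)
    Rcpp::stop("ill-conditioned AR normal equations (rcond = %g)", rc);

  arma::vec phi = arma::solve(R, r, arma::solve_opts::likely_sympd);
  double rss = C(0, 0) - arma::dot(phi, r);
  if (rss < 0) rss = 0;  // numerical guard
  const double sigma2 = rss / (n - p);

  return Rcpp::List::create(Rcpp::Named("phi") = phi,
                            Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("rcond") = rc);
}
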