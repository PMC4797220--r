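// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Restricted log-likelihood profiled over the variance ratio gamma, in the
// eigenbasis of the relationship matrix: lam = eigenvalues, ty = U'y,
// tX = U'X. Returns a matrix with one row per gamma: loglik, sigma_e2.
// Constant convention matches the R-side null model (see remlscan.R).
// [[Rcpp::export]]
NumericMatrix reml_profile_grid(const arma::vec& lam, const arma::vec& ty,
                                const arma::mat& tX, const arma::vec& gammas) {
  const int n = ty.n_elem, p = tX.n_cols;
  NumericMatrix out(gammas.n_elem, 2);
  for (arma::uword g = 0; g < gammas.n_elem; ++g) {
    const double gam = gammas[g];
    arma::vec w = 1.0 / (1.0 + gam * lam);
    arma::mat XtWX = tX.t() * (tX.each_col() % w);
    arma::vec XtWy = tX.t() * (w % ty);
    arma::mat R;
    double ll = -arma::datum::inf, s2 = NA_REAL;
    if (arma::chol(R, XtWX)) {
      arma::vec beta = arma::solve(arma::trimatu(R),
                                   arma::solve(arma::trimatl(R.t()), XtWy));
      arma::vec r = ty - tX * beta;
      double rss = arma::dot(w, r % r);
      if (rss > 0) {
        s2 = rss / (n - p);
        double logdet_H = arma::sum(arma::log1p(gam * lam));
        double logdet_XtWX = 2.0 * arma::sum(arma::log(R.diag()));
        ll = -0.5 * ((n - p) * std::log(s2) + logdet_H + logdet_XtWX + (n - p));
      }
    }
    out(g, 0) = ll;
    out(g, 1) = s2;
  }
  return out;
}

// Symmetric eigendecomposition with eigenvalues in descending order.
// [[Rcpp::export]]
List sym_eigen(const arma::mat& D) {
  arma::vec val;
  arma::mat vec;
  if (!arma::eig_sym(val, vec, arma::symmatu(D), "dc"))
    stop("eigendecomposition failed");
  arma::vec rv = arma::reverse(val);
  return List::create(
      _["values"] = NumericVector(rv.begin(), rv.end()),
      _["vectors"] = wrap(arma::fliplr(vec)));
}
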