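// REML criterion for the two-level model with random intercept and slope and
// ID or homogeneous AR(1) residual covariance, evaluated blockwise per
// subject via the Woodbury identity. The per-subject data enter only through
// lag cross-products of W_i = [X_i, Z_i, y_i]:
//   C0 = W'W,  C1s = sum_{t>1} (w_t w_{t-1}' + w_{t-1} w_t'),
//   B  = w_1 w_1' + w_L w_L',
// because the AR(1) inverse correlation is tridiagonal:
//   V^{-1} = [ (1+rho^2) C0 - rho C1s - rho^2 B ] / (1 - rho^2)  (as a quadratic
// form), so W' R^{-1} W = (C0 - rho C1s + rho^2 (C0 - B)) / ((1-rho^2) sigma2).
// rho = 0 gives the ID structure. Cost per evaluation is O(N q^3), q = 7.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List reml_eval_cpp(const arma::cube& C0, const arma::cube& C1s,
                         const arma::cube& B, const arma::ivec& Ls,
                         int nf, int nr, const arma::mat& G, double sigma2,
                         double rho) {
  const arma::uword N = C0.n_slices;
  const int q = nf + nr + 1;
  const double bad = 1e10;

  arma::mat Ginv;
  double logdetG;
  {
    arma::mat Lg;
    if (!arma::chol(Lg, G, "lower"))
      return Rcpp::List::create(Rcpp::Named("neg2") = bad);
    logdetG = 2.0 * arma::sum(arma::log(Lg.diag()));
    Ginv = arma::inv_sympd(G);
  }
  if (sigma2 <= 0.0 || std::abs(rho) >= 1.0)
    return Rcpp::List::create(Rcpp::Named("neg2") = bad);

  const double omr2 = 1.0 - rho * rho;
  const double scale = 1.0 / (omr2 * sigma2);
  const arma::uvec ix = arma::regspace<arma::uvec>(0, nf - 1);
  const arma::uvec iz = arma::regspace<arma::uvec>(nf, nf + nr - 1);
  arma::uvec ixy(nf + 1);
  for (int j = 0; j < nf; ++j) ixy(j) = j;
  ixy(nf) = nf + nr;

  arma::mat XtSX(nf, nf, arma::fill::zeros);
  arma::vec XtSy(nf, arma::fill::zeros);
  double ytSy = 0.0, logdetsum = 0.0;
  long ntot = 0;

  for (arma::uword i = 0; i < N; ++i) {
    arma::mat T = scale * (C0.slice(i) - rho * C1s.slice(i) +
                           (rho * rho) * (C0.slice(i) - B.slice(i)));
    arma::mat M = Ginv + T.submat(iz, iz);
    arma::mat Lm;
    if (!arma::chol(Lm, M, "lower"))
      return Rcpp::List::create(Rcpp::Named("neg2") = bad);
    double logdetM = 2.0 * arma::sum(arma::log(Lm.diag()));
    arma::mat K = T.submat(iz, ixy);                   // nr x (nf+1)
    arma::mat U = arma::solve(arma::trimatl(Lm), K,
                              arma::solve_opts::fast); // Lm^{-1} K
    arma::mat Adj = T.submat(ixy, ixy) - U.t() * U;

    XtSX += Adj.submat(0, 0, nf - 1, nf - 1);
    XtSy += Adj.submat(0, nf, nf - 1, nf);
    ytSy += Adj(nf, nf);
    logdetsum += Ls(i) * std::log(sigma2) + (Ls(i) - 1) * std::log(omr2) +
                 logdetG + logdetM;
    ntot += Ls(i);
  }

  arma::mat Lx;
  if (!arma::chol(Lx, XtSX, "lower"))
    return Rcpp::List::create(Rcpp::Named("neg2") = bad);
  double logdetX = 2.0 * arma::sum(arma::log(Lx.diag()));
  arma::vec gamma =
      arma::solve(arma::trimatu(Lx.t()),
                  arma::solve(arma::trimatl(Lx), XtSy, arma::solve_opts::fast),
                  arma::solve_opts::fast);
  double quad = ytSy - arma::dot(XtSy, gamma);
  double neg2 = logdetsum + logdetX + quad +
                (ntot - nf) * std::log(2.0 * M_PI);
  if (!std::isfinite(neg2))
    return Rcpp::List::create(Rcpp::Named("neg2") = bad);

  return Rcpp::List::create(Rcpp::Named("neg2") = neg2,
                            Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("XtSX") = XtSX);
}
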