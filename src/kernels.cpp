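#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw visible vectors given hidden configurations, one multivariate normal
// per row. Hc (n x Mc) and Hm (n x Mm) may be binary samples or mean-field
// probabilities; Z holds pre-drawn standard normals (pass zeros to get the
// deterministic conditional mean). With unit_prec the identity is added to
// the precision matrix (proper-density conditional used during CD training);
// otherwise a relative ridge keeps the inversion well posed.
// [[Rcpp::export]]
arma::mat cpp_sample_visible(const arma::mat& Hc, const arma::mat& Hm,
                             const arma::mat& C, const arma::mat& P,
                             const arma::mat& W, const arma::mat& Z,
                             double ridge, bool unit_prec) {
  const arma::uword n = Hc.n_rows, D = C.n_rows;
  arma::mat S = -(Hc * P.t());   // n x F, nonnegative since P <= 0
  arma::mat B = Hm * W.t();      // n x D, rows are W h_m
  arma::mat V(n, D);
  arma::mat M(D, D), R(D, D);
  for (arma::uword i = 0; i < n; ++i) {
    M = C * arma::diagmat(S.row(i)) * C.t();
    if (unit_prec) {
      M.diag() += 1.0;
    } else {
      double tr = arma::trace(M);
      M.diag() += ridge * (tr > 0 ? tr / D : 1.0);
    }
    if (!arma::chol(R, M)) Rcpp::stop("degenerate-state");
    // precision M = R'R; mean = M^{-1} W h_m; draw = mean + R^{-1} z
    arma::vec mu = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), B.row(i).t()));
    V.row(i) = (mu + arma::solve(arma::trimatu(R), Z.row(i).t())).t();
  }
  return V;
}

// Sample a time-inhomogeneous Markov chain. cum is a K x K x M stack of
// row-cumulative transition matrices, idx gives the (1-based) slice used at
// each step, u holds pre-drawn uniforms so the C++ side owns no RNG state.
// The first output state is drawn from row `init` of slice idx[0].
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(const arma::cube& cum, const IntegerVector& idx,
                               const NumericVector& u, int init) {
  const int n = idx.size();
  const int K = cum.n_rows;
  IntegerVector out(n);
  int s = init - 1;
  for (int t = 0; t < n; ++t) {
    const arma::mat& Tm = cum.slice(idx[t] - 1);
    const double r = u[t];
    int j = 0;
    while (j < K - 1 && Tm(s, j) < r) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}
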