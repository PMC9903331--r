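#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Batch orthogonal matching pursuit against a fixed dictionary.
//
// D must have (approximately) unit-norm columns; checked on the R side.
// Uses the precomputed Gram matrix so the per-column cost after the one-off
// D'Y product is O(L^2 k), the standard batch-OMP formulation.
//
// resid_tol2 is the squared l2 residual threshold for early exit.
// Returns the k x N coefficient matrix (dense; k is small).
// [[Rcpp::export(name = ".omp_encode_cpp")]]
arma::mat omp_encode_cpp(const arma::mat& D, const arma::mat& Y,
                         const int L, const double resid_tol2) {
  const uword k = D.n_cols, N = Y.n_cols;
  mat S(k, N, fill::zeros);
  if (L <= 0 || k == 0 || N == 0) return S;

  const mat G = D.t() * D;     // k x k
  const mat DtY = D.t() * Y;   // k x N
  const rowvec ynorm2 = sum(square(Y), 0);
  const int Lmax = std::min<int>(L, (int)k);

  for (uword i = 0; i < N; ++i) {
    const vec alpha0 = DtY.col(i);
    vec alpha = alpha0;
    double eps = ynorm2(i);
    uvec support(Lmax);
    int ns = 0;
    vec coef;

    for (int t = 0; t < Lmax; ++t) {
      if (eps <= resid_tol2) break;
      const uword j = index_max(abs(alpha));
      bool dup = false;
      for (int q = 0; q < ns; ++q) if (support(q) == j) { dup = true; break; }
      if (dup) break;  // numerically exhausted
      support(ns++) = j;
      const uvec s = support.head(ns);
      const mat Gs = G.submat(s, s);
      bool ok = solve(coef, Gs, alpha0.elem(s),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) { ns--; break; }
      alpha = alpha0 - G.cols(s) * coef;
      eps = ynorm2(i) - dot(coef, alpha0.elem(s));
      if (eps < 0) eps = 0;
    }
    if (ns > 0) {
      for (int q = 0; q < ns; ++q) S(support(q), i) = coef(q);
    }
  }
  return S;
}
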