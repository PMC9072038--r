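#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// var(y) = s1 * (Omega1 (x) J_T) + s2 * (I_m (x) Omega2) + diag(d),
// area-major / time-minor stacking: row index = (i-1)*T + t.
// Returns false when I - r1*W is numerically singular.
static bool build_V(mat& V, const vec& d, const mat& W, double s1, double r1,
                    double s2, double r2, int T, int m) {
  const int n = m * T;
  V.zeros(n, n);
  if (s1 > 0.0) {
    mat A = eye(m, m) - r1 * W;
    mat P = A.t() * A;
    mat O1;
    if (!inv_sympd(O1, P)) return false;
    V += s1 * kron(O1, ones(T, T));
  }
  if (s2 > 0.0) {
    const double c = 1.0 / (1.0 - r2 * r2);
    mat O2(T, T);
    for (int t = 0; t < T; ++t)
      for (int s = 0; s < T; ++s) O2(t, s) = c * std::pow(r2, std::abs(t - s));
    for (int i = 0; i < m; ++i)
      V.submat(i * T, i * T, (i + 1) * T - 1, (i + 1) * T - 1) += s2 * O2;
  }
  V.diag() += d;
  return true;
}

// Restricted log-likelihood of the stacked mixed model at tau =
// (s1, r1, s2, r2):
//   l_R = -1/2 [ (n-p) log 2*pi + log|V| + log|X'V^-1 X| + y'Py ].
// One Cholesky factorization of V per call; no explicit inverses.
// Returns NA on factorization failure so the optimizer can penalize.
// [[Rcpp::export]]
double reml_loglik_cpp(const arma::vec& y, const arma::mat& X,
                       const arma::vec& d, const arma::mat& W, double s1,
                       double r1, double s2, double r2, int T) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int m = n / T;
  if ((int)W.n_rows != m || (int)W.n_cols != m) return NA_REAL;
  mat V;
  if (!build_V(V, d, W, s1, r1, s2, r2, T, m)) return NA_REAL;
  mat L;
  if (!chol(L, V, "lower")) return NA_REAL;
  mat Lx = solve(trimatl(L), X);
  vec ly = solve(trimatl(L), y);
  mat M = Lx.t() * Lx;  // X'V^-1 X
  mat Lm;
  if (!chol(Lm, M, "lower")) return NA_REAL;
  vec xty = Lx.t() * ly;  // X'V^-1 y
  vec beta = solve(trimatu(Lm.t()), solve(trimatl(Lm), xty));
  const double logdetV = 2.0 * sum(log(L.diag()));
  const double logdetM = 2.0 * sum(log(Lm.diag()));
  const double yPy = dot(ly, ly) - dot(xty, beta);
  return -0.5 * ((n - p) * std::log(2.0 * M_PI) + logdetV + logdetM + yPy);
}
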