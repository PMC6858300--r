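#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Squared Euclidean distances between rows of X (n x d) and rows of C (c x d).
static mat sq_dist(const mat& X, const mat& C, const vec& x2) {
  vec c2 = sum(square(C), 1);
  mat D2 = repmat(x2, 1, C.n_rows) + repmat(c2.t(), X.n_rows, 1) - 2.0 * (X * C.t());
  D2.elem(find(D2 < 0)).zeros();
  return D2;
}

// Membership update: u_ij = d_ij^{-2/(m-1)} / sum_k d_ik^{-2/(m-1)},
// with the crisp convention for samples coincident with a centre.
static mat memberships(const mat& D2, double m, double eps) {
  const double e = 1.0 / (m - 1.0);
  mat W = pow(D2 + datum::eps, -e);
  // coincident samples: membership 1 to the first coincident centre
  uvec hit = find(min(D2, 1) < eps);
  for (uword idx = 0; idx < hit.n_elem; ++idx) {
    uword i = hit(idx);
    rowvec r(D2.n_cols, fill::zeros);
    r(index_min(D2.row(i))) = 1.0;
    W.row(i) = r;
  }
  return W.each_col() / sum(W, 1);
}

// Fuzzy c-means by alternating optimisation from fixed initial centres.
// Returns centres, memberships, the objective trace and a convergence flag.
// [[Rcpp::export(name = ".cmeans_core")]]
Rcpp::List cmeans_core(const arma::mat& X, const arma::mat& C0, double m,
                       double tol, int max_iter) {
  const double eps = 1e-12;
  mat C = C0;
  vec x2 = sum(square(X), 1);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  mat U;
  double J_prev = datum::inf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    mat D2 = sq_dist(X, C, x2);
    U = memberships(D2, m, eps);
    mat Um = pow(U, m);
    double J = accu(Um % D2);
    trace.push_back(J);
    if (std::isfinite(J_prev)) {
      double denom = std::max(std::abs(J_prev), eps);
      if (std::abs(J_prev - J) / denom < tol) { converged = true; ++it; break; }
    }
    J_prev = J;
    // centre update; empty (all-zero weight) clusters keep their position
    rowvec w = sum(Um, 0);
    mat Cnew = Um.t() * X;
    for (uword k = 0; k < Cnew.n_rows; ++k) {
      if (w(k) > eps) Cnew.row(k) /= w(k); else Cnew.row(k) = C.row(k);
    }
    C = Cnew;
  }
  return Rcpp::List::create(
    Rcpp::Named("centres") = C,
    Rcpp::Named("membership") = U,
    Rcpp::Named("objective") = trace.empty() ? NA_REAL : trace.back(),
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
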