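// Graphical lasso: block coordinate descent over columns of the covariance
// estimate W, each block solved by an inner lasso coordinate descent
// (Friedman, Hastie & Tibshirani style). The diagonal is not penalised, so
// at the optimum diag(W) = diag(S). Warm starts carry W and the regression
// coefficients along a descending penalty path.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Inner lasso: minimise 0.5 b'Vb - s12'b + lam * ||b||_1.
// V must be positive definite (principal submatrix of a PD W).
static void lasso_cd(const mat& V, const vec& s12, double lam, vec& beta,
                     double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = beta(k);
      // residual gradient with beta(k) removed
      double r = s12(k) - dot(V.col(k), beta) + V(k, k) * old;
      double bk = soft_threshold(r, lam) / V(k, k);
      if (bk != old) {
        beta(k) = bk;
        double d = std::fabs(bk - old);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

// One glasso solve at fixed lam, warm-started from W and Beta (p x p matrix
// whose column j holds the regression coefficients of the other variables;
// row j of column j is ignored). Returns iterations used, -1 on failure.
static int glasso_fit(const mat& S, double lam, mat& W, mat& Beta,
                      mat& Theta, double tol, int maxit) {
  const uword p = S.n_rows;
  if (p == 1) {
    W = S;
    Theta = mat(1, 1, fill::value(1.0 / S(0, 0)));
    return 0;
  }
  // absolute convergence threshold scaled by average |off-diagonal of S|
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) sbar += std::fabs(S(i, j));
  sbar /= double(p * (p - 1));
  double thr = tol * std::max(sbar, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  int iters = maxit;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = Beta.col(j);
      beta = beta.elem(idx);
      lasso_cd(V, s12, lam, beta, thr / 10.0, 10 * maxit);
      vec w12 = V * beta;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        Beta(idx(k), j) = beta(k);
      }
    }
    if (dmax < thr) { iters = it + 1; break; }
  }

  // back out the precision matrix from the final regressions
  Theta.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = Beta.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - dot(w12, beta);
    if (!(denom > 0.0)) return -1;
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword k = 0; k < idx.n_elem; ++k)
      Theta(idx(k), j) = -beta(k) * tjj;
  }
  // symmetrise; an entry is exactly zero iff both regressions excluded it
  Theta = 0.5 * (Theta + Theta.t());
  return iters;
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-8, int maxit = 1000) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  mat W = S;
  mat Beta(p, p, fill::zeros);
  Rcpp::List thetas(nl), ws(nl);
  Rcpp::IntegerVector iters(nl);
  for (uword l = 0; l < nl; ++l) {
    mat Theta;
    int it = glasso_fit(S, lambdas(l), W, Beta, Theta, tol, maxit);
    if (it < 0)
      Rcpp::stop("graphical lasso failed at lambda = %g (non-positive pivot)",
                 lambdas(l));
    thetas[l] = Theta;
    ws[l] = W;          // copy of current warm state at this lambda
    iters[l] = it;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("w") = ws,
                            Rcpp::Named("iters") = iters);
}
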