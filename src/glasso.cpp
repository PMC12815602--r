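// Graphical lasso by block coordinate descent (Friedman-style), with the
// diagonal unpenalized: the estimated covariance keeps w_ii = s_ii and only
// off-diagonal precision entries are L1-shrunk.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Solve the column lasso  min_b 0.5 b'W11 b - s12'b + lam |b|_1
// by cyclic coordinate descent, warm-started from beta.
static void lasso_cd(const mat& W11, const vec& s12, double lam,
                     vec& beta, int maxit, double tol) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double del = 0.0;
    for (uword k = 0; k < q; ++k) {
      double r = s12(k) - dot(W11.row(k), beta) + W11(k, k) * beta(k);
      double bnew = soft(r, lam) / W11(k, k);
      double d = std::abs(bnew - beta(k));
      if (d > del) del = d;
      beta(k) = bnew;
    }
    if (del < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     Rcpp::Nullable<Rcpp::NumericMatrix> warm_W = R_NilValue,
                     int maxit = 500, double tol = 1e-9,
                     int inner_maxit = 2000, double inner_tol = 1e-11) {
  const uword p = S.n_rows;
  mat W = warm_W.isNotNull() ? mat(Rcpp::as<mat>(warm_W.get())) : mat(S);
  W.diag() = S.diag();               // diagonal unpenalized
  mat Beta(p - 1, p, fill::zeros);   // per-column regression coefficients

  // initialize Beta consistently with warm W (zeros are fine otherwise)
  const double soff = p > 1 ? accu(abs(S - diagmat(S.diag()))) / (p * (p - 1)) : 0.0;
  const double crit = tol * std::max(soff, 1e-12);

  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    double maxdel = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(linspace<uvec>(0, p - 1, p) != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = Beta.col(j);
      lasso_cd(W11, s12, lambda, beta, inner_maxit, inner_tol);
      Beta.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > maxdel) maxdel = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (maxdel < crit) break;
  }
  bool converged = iter <= maxit;
  if (iter > maxit) iter = maxit;

  // Recover the precision matrix from the final (W, Beta):
  // theta_jj = 1 / (w_jj - w12' beta_j), theta_12 = -beta_j * theta_jj.
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(linspace<uvec>(0, p - 1, p) != j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double tjj = 1.0 / (W(j, j) - dot(w12, Beta.col(j)));
    Theta(j, j) = tjj;
    for (uword k = 0; k < p - 1; ++k) Theta(idx(k), j) = -Beta(k, j) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("w_cov") = W,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged);
}

// Case-resampling bootstrap for the two-equation recursive path model.
// Xm (n x km) -> m, Xy (n x ky) -> y; idx is an n x B matrix of 1-based
// row indices. Returns B x (km + ky) stacked OLS coefficients.
// [[Rcpp::export(name = ".path_boot")]]
arma::mat path_boot(const arma::mat& Xm, const arma::vec& m,
                    const arma::mat& Xy, const arma::vec& y,
                    const arma::umat& idx) {
  const uword B = idx.n_cols, km = Xm.n_cols, ky = Xy.n_cols;
  mat out(B, km + ky);
  for (uword b = 0; b < B; ++b) {
    uvec rows = idx.col(b) - 1;
    mat Xmb = Xm.rows(rows), Xyb = Xy.rows(rows);
    vec cm = solve(Xmb.t() * Xmb, Xmb.t() * m.elem(rows), solve_opts::likely_sympd);
    vec cy = solve(Xyb.t() * Xyb, Xyb.t() * y.elem(rows), solve_opts::likely_sympd);
    out.row(b).cols(0, km - 1) = cm.t();
    out.row(b).cols(km, km + ky - 1) = cy.t();
  }
  return out;
}
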