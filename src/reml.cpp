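// REML kernel for the per-SNP spline linear mixed model.
//
// Marginal covariance of one individual's observations:
//   V_i = sigma2 * W_i,   W_i = Z_i A Z_i' + D_i S_i(phi) D_i
// with Z_i = [1, age-8], A = G / sigma2 (scaled random-effect covariance),
// S_i the CAR(1) correlation phi^|t_j - t_k|, and D_i a diagonal residual
// SD multiplier (1 for clinic rows, `mult` for questionnaire rows).
// sigma2 and beta are profiled out, so the optimiser only sees (A, phi, mult).

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build W_i for one cluster (rows s..e, inclusive, 0-based).
static mat cluster_W(const mat& Z, const vec& times, const vec& src,
                     uword s, uword e, const mat& A, double phi,
                     double mult, double nugget) {
  uword m = e - s + 1;
  mat W(m, m);
  bool dup = false;
  for (uword j = 0; j < m; ++j) {
    double dj = (src[s + j] > 0.5) ? mult : 1.0;
    for (uword k = 0; k <= j; ++k) {
      double dt = std::fabs(times[s + j] - times[s + k]);
      double dk = (src[s + k] > 0.5) ? mult : 1.0;
      double v = dj * dk * ((phi == 0.0) ? (dt == 0.0 ? 1.0 : 0.0)
                                         : std::pow(phi, dt));
      W(j, k) = v;
      W(k, j) = v;
      if (j != k && dt == 0.0) dup = true;
    }
  }
  if (dup) W.diag() += nugget;
  mat Zc = Z.rows(s, e);
  W += Zc * A * Zc.t();
  return W;
}

// One pass over clusters: accumulate X'W^-1 X, X'W^-1 y, y'W^-1 y, log|W|.
// [[Rcpp::export]]
Rcpp::List reml_core(const arma::mat& X, const arma::vec& y,
                     const arma::mat& Z, const arma::vec& times,
                     const arma::vec& src, const arma::uvec& starts,
                     const arma::uvec& ends, const arma::mat& A,
                     double phi, double mult, double nugget) {
  uword p = X.n_cols, nc = starts.n_elem;
  mat XtWiX(p, p, fill::zeros);
  vec XtWiy(p, fill::zeros);
  double ytWiy = 0.0, logdetW = 0.0;
  for (uword c = 0; c < nc; ++c) {
    uword s = starts[c], e = ends[c];
    mat W = cluster_W(Z, times, src, s, e, A, phi, mult, nugget);
    mat L;
    if (!chol(L, W, "lower"))
      return Rcpp::List::create(Rcpp::Named("ok") = false);
    mat Xs = solve(trimatl(L), X.rows(s, e));
    vec ys = solve(trimatl(L), y.subvec(s, e));
    XtWiX += Xs.t() * Xs;
    XtWiy += Xs.t() * ys;
    ytWiy += dot(ys, ys);
    logdetW += 2.0 * sum(log(L.diag()));
  }
  mat R;
  if (!chol(R, XtWiX))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  vec beta = solve(trimatu(R), solve(trimatl(R.t()), XtWiy));
  double rWr = ytWiy - dot(XtWiy, beta);
  double ldXtWiX = 2.0 * sum(log(R.diag()));
  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("XtWiX") = XtWiX,
      Rcpp::Named("XtWiy") = XtWiy, Rcpp::Named("beta") = beta,
      Rcpp::Named("rWr") = rWr, Rcpp::Named("logdetW") = logdetW,
      Rcpp::Named("logdetXtWiX") = ldXtWiX);
}

// Per-cluster working-model covariance blocks of the contrast scores:
//   Q_i = (M K_i M)[idx, idx],  K_i = X_i' W_i^-1 X_i,  M = (X'W^-1X)^-1.
// Under the working model the CR2-adjusted cluster score for the selected
// coefficients has covariance sigma2 * Q_i; these blocks feed the
// Satterthwaite effective-df estimate for the multi-df Wald tests.
// [[Rcpp::export]]
arma::cube cluster_score_blocks(const arma::mat& X, const arma::mat& Z,
                                const arma::vec& times, const arma::vec& src,
                                const arma::uvec& starts,
                                const arma::uvec& ends, const arma::mat& A,
                                double phi, double mult, double nugget,
                                const arma::mat& M, const arma::uvec& idx) {
  uword nc = starts.n_elem, k = idx.n_elem;
  cube Q(k, k, nc);
  for (uword c = 0; c < nc; ++c) {
    uword s = starts[c], e = ends[c];
    mat W = cluster_W(Z, times, src, s, e, A, phi, mult, nugget);
    mat L = chol(W, "lower");
    mat Xs = solve(trimatl(L), X.rows(s, e));
    mat K = Xs.t() * Xs;
    mat T = M * K * M;
    Q.slice(c) = T.submat(idx, idx);
  }
  return Q;
}

// Cluster-level sandwich meat on the W scale:
//   B_W = sum_i (X_i' W_i^-1 r_i*)(X_i' W_i^-1 r_i*)'
// The sigma2 factors cancel in A^-1 B A^-1, so
//   cov_robust = (X'W^-1X)^-1 B_W (X'W^-1X)^-1.
// adjust: 0 = CR0 (raw residuals), 1 = CR1 (J/(J-1) inflation),
// 2 = CR2 (Bell-McCaffrey): r_i* = A_i r_i with A_i the working-model
// leverage adjustment satisfying A_i (W_i - X_i M X_i') A_i' = W_i,
// M = (X'W^-1X)^-1, which removes the downward bias of the plain
// estimator when the working model holds.
// [[Rcpp::export]]
arma::mat cluster_meat(const arma::mat& X, const arma::vec& y,
                       const arma::mat& Z, const arma::vec& times,
                       const arma::vec& src, const arma::uvec& starts,
                       const arma::uvec& ends, const arma::mat& A,
                       double phi, double mult, double nugget,
                       const arma::vec& beta, int adjust,
                       const arma::mat& M) {
  uword p = X.n_cols, nc = starts.n_elem;
  mat B(p, p, fill::zeros);
  for (uword c = 0; c < nc; ++c) {
    uword s = starts[c], e = ends[c];
    mat W = cluster_W(Z, times, src, s, e, A, phi, mult, nugget);
    mat Xc = X.rows(s, e);
    vec r = y.subvec(s, e) - Xc * beta;
    if (adjust == 2) {
      // P = I - W^-1/2 Xc M Xc' W^-1/2, symmetric PSD; the adjusted
      // residual is W^1/2 P^-1/2 W^-1/2 r (pseudo-inverted below a floor)
      mat Ws = sqrtmat_sympd(W);
      mat Wsinv = inv_sympd(Ws);
      mat P = eye(W.n_rows, W.n_cols) - Wsinv * (Xc * M * Xc.t()) * Wsinv;
      vec ev; mat V;
      eig_sym(ev, V, (P + P.t()) / 2.0);
      vec evh(ev.n_elem);
      for (uword j = 0; j < ev.n_elem; ++j)
        evh[j] = (ev[j] > 1e-8) ? 1.0 / std::sqrt(ev[j]) : 0.0;
      mat Pinvh = V * diagmat(evh) * V.t();
      r = Ws * (Pinvh * (Wsinv * r));
    }
    vec u = solve(W, r, solve_opts::likely_sympd);
    vec g = Xc.t() * u;
    double w = (adjust == 1) ? static_cast<double>(nc) / (nc - 1.0) : 1.0;
    B += w * (g * g.t());
  }
  return B;
}
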