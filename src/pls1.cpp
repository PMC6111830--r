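// NIPALS PLS1 core. All routines work on mean-centered copies internally;
// callers pass raw X (n x p) and y (n). Coefficients are returned on the
// centered scale for every component count 1..max_nlv so that coefficient
// paths (needed for the jaggedness criterion) come from a single pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fit PLS1 on centered data, filling B (p x A) with cumulative coefficient
// vectors. Returns the number of components actually extracted (deflation
// can exhaust the signal early on low-rank problems); remaining columns of
// B repeat the last valid one so downstream indexing stays total.
static int nipals_pls1(const mat& Xc, const vec& yc, int max_nlv, mat& B) {
  const uword p = Xc.n_cols;
  mat W(p, max_nlv), P(p, max_nlv);
  vec q(max_nlv);
  mat Xa = Xc;
  vec ya = yc;
  const double tol = 1e-12 * std::max(1.0, norm(yc));

  int a = 0;
  for (; a < max_nlv; ++a) {
    vec w = Xa.t() * ya;
    double wn = norm(w);
    if (wn < tol) break;
    w /= wn;
    vec t = Xa * w;
    double tt = dot(t, t);
    if (tt < 1e-300) break;
    vec pa = Xa.t() * t / tt;
    double qa = dot(ya, t) / tt;
    W.col(a) = w;
    P.col(a) = pa;
    q(a) = qa;
    Xa -= t * pa.t();
    ya -= qa * t;

    // cumulative coefficients: B_a = W (P'W)^{-1} q over first a+1 comps
    mat Wa = W.cols(0, a), Pa = P.cols(0, a);
    vec qa_ = q.subvec(0, a);
    mat R = Pa.t() * Wa;  // (a+1) x (a+1), unit upper triangular up to scale
    vec g;
    bool ok = solve(g, R, qa_, solve_opts::no_approx);
    if (!ok) break;
    B.col(a) = Wa * g;
  }
  if (a == 0) {
    B.zeros();
    return 0;
  }
  for (int j = a; j < max_nlv; ++j) B.col(j) = B.col(a - 1);
  return a;
}

// [[Rcpp::export(name = ".pls1_path")]]
Rcpp::List pls1_path(const arma::mat& X, const arma::vec& y, int max_nlv) {
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat B(X.n_cols, (uword)max_nlv, fill::zeros);
  int a = nipals_pls1(Xc, yc, max_nlv, B);
  return Rcpp::List::create(
    Rcpp::Named("beta") = B,
    Rcpp::Named("x_mean") = xm.t(),
    Rcpp::Named("y_mean") = ym,
    Rcpp::Named("ncomp") = a);
}

// Leave-one-out predictions for every component count 1..max_nlv.
// Each held-out sample is predicted by a model (including centering)
// that never saw it. Returns an n x max_nlv matrix.
// [[Rcpp::export(name = ".pls1_loo")]]
arma::mat pls1_loo(const arma::mat& X, const arma::vec& y, int max_nlv) {
  const uword n = X.n_rows, p = X.n_cols;
  mat pred(n, (uword)max_nlv);
  mat Xi(n - 1, p);
  vec yi(n - 1);
  mat B(p, (uword)max_nlv);
  for (uword i = 0; i < n; ++i) {
    uword k = 0;
    for (uword r = 0; r < n; ++r) {
      if (r == i) continue;
      Xi.row(k) = X.row(r);
      yi(k) = y(r);
      ++k;
    }
    rowvec xm = mean(Xi, 0);
    double ym = mean(yi);
    mat Xc = Xi.each_row() - xm;
    vec yc = yi - ym;
    B.zeros();
    nipals_pls1(Xc, yc, max_nlv, B);
    rowvec xd = X.row(i) - xm;
    pred.row(i) = xd * B + ym;
  }
  return pred;
}
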