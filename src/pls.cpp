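// PLS1 (single-response partial least squares) kernels used by the
// cross-validation loops: SiPLS evaluates C(20,3) = 1140 interval unions by
// leave-one-out CV, and permutation testing refits the model a few hundred
// times, so the inner fit/predict path is compiled.
//
// NIPALS for one response is non-iterative: per component
//   w = X'y / ||X'y||,  t = Xw,  p = X't/t't,  q = y't/t't,
// with deflation X <- X - t p', y <- y - q t. Predictions for 1..A
// components come from the cumulative coefficients b_A = W (P'W)^-1 q.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void centre_scale(const mat& Xtr, bool scale, rowvec& xm, rowvec& xs) {
  xm = mean(Xtr, 0);
  xs = rowvec(Xtr.n_cols, fill::ones);
  if (scale) {
    xs = stddev(Xtr, 0, 0);
    xs.elem(find(xs < 1e-12)).ones();
  }
}

// Fit on (Xtr, ytr), return predictions for Xte at every component count
// 1..nlv (columns). If the rank is exhausted earlier, remaining columns
// repeat the last valid prediction.
static mat pls1_predict_core(const mat& Xtr, const vec& ytr, const mat& Xte,
                             int nlv, bool scale) {
  rowvec xm, xs;
  centre_scale(Xtr, scale, xm, xs);
  mat X = Xtr.each_row() - xm;  X.each_row() /= xs;
  mat Xt = Xte.each_row() - xm; Xt.each_row() /= xs;
  double ym = mean(ytr);
  vec y = ytr - ym;

  const int p = X.n_cols;
  mat W(p, nlv, fill::zeros), P(p, nlv, fill::zeros);
  vec q(nlv, fill::zeros);
  mat preds(Xte.n_rows, nlv);
  int got = 0;
  for (int a = 0; a < nlv; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < 1e-13) break;
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-13) break;
    vec pl = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    X -= t * pl.t();
    y -= qa * t;
    W.col(a) = w; P.col(a) = pl; q(a) = qa;
    mat Wa = W.cols(0, a), Pa = P.cols(0, a);
    vec b = Wa * solve(Pa.t() * Wa, q.subvec(0, a));
    preds.col(a) = ym + Xt * b;
    got = a + 1;
  }
  if (got == 0) preds.fill(ym);
  for (int a = got; a < nlv; ++a) preds.col(a) = preds.col(std::max(got, 1) - 1);
  return preds;
}

// [[Rcpp::export(name = ".pls1_predict_cpp")]]
arma::mat pls1_predict_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                           const arma::mat& Xte, int nlv, bool scale) {
  return pls1_predict_core(Xtr, ytr, Xte, nlv, scale);
}

// Leave-one-out cross-validated predictions: row i holds the predictions
// for sample i from the model fitted without it, at 1..nlv components.
// [[Rcpp::export(name = ".pls1_loo_cpp")]]
arma::mat pls1_loo_cpp(const arma::mat& X, const arma::vec& y, int nlv,
                       bool scale) {
  const int n = X.n_rows;
  mat preds(n, nlv);
  uvec all = regspace<uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    uvec tr = find(all != (uword)i);
    preds.row(i) = pls1_predict_core(X.rows(tr), y.elem(tr), X.row(i),
                                     nlv, scale);
  }
  return preds;
}
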