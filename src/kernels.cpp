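// Numerical kernels: PLS1 (NIPALS) with leave-one-out cross-validation and
// the pairwise binary-linear-regression LOOCV scan. Both are called in tight
// loops (hundreds of windows, hundreds of thousands of wavelength pairs) and
// are kept in C++ for that reason; all user-facing validation lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Residual-norm floor below which further components carry no information.
static const double PLS_TOL = 1e-12;

// Train PLS1 on (Xtr, ytr), predict Xte for every factor count 1..Fmax.
// preds is nte x Fmax. If the X residual is exhausted before Fmax the
// remaining columns repeat the last attainable prediction.
static void pls1_train_predict(const mat& Xtr, const vec& ytr, const mat& Xte,
                               int Fmax, mat& preds) {
  rowvec xm = mean(Xtr, 0);
  double ym = mean(ytr);
  mat Xc = Xtr.each_row() - xm;
  vec yc = ytr - ym;
  mat Ec = Xte.each_row() - xm;   // test rows, deflated alongside Xc
  vec acc(Xte.n_rows, fill::zeros);
  int f = 0;
  for (; f < Fmax; ++f) {
    if (norm(Xc, "fro") < PLS_TOL) break;
    vec w = Xc.t() * yc;
    double nw = norm(w);
    if (nw < PLS_TOL) break;
    w /= nw;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < PLS_TOL) break;
    vec p = Xc.t() * t / tt;
    double q = dot(yc, t) / tt;
    Xc -= t * p.t();
    yc -= q * t;
    vec t0 = Ec * w;
    acc += q * t0;
    Ec -= t0 * p.t();
    preds.col(f) = acc + ym;
  }
  for (; f < Fmax; ++f) preds.col(f) = acc + ym;
}

// Leave-one-out cross-validated predictions for factor counts 1..Fmax.
// Returns an n x Fmax matrix; row i is predicted by a model that never saw
// sample i.
// [[Rcpp::export]]
arma::mat pls1_loocv_cpp(const arma::mat& X, const arma::vec& y, int Fmax) {
  const uword n = X.n_rows;
  mat out(n, Fmax);
  for (uword i = 0; i < n; ++i) {
    uvec idx = regspace<uvec>(0, n - 1);
    idx.shed_row(i);
    mat preds(1, Fmax);
    pls1_train_predict(X.rows(idx), y(idx), X.row(i), Fmax, preds);
    out.row(i) = preds.row(0);
  }
  return out;
}

// Full-data PLS1 fit: returns the regression vector (on raw absorbance),
// the column means, y mean, and the number of components actually extracted.
// [[Rcpp::export]]
Rcpp::List pls1_fit_cpp(const arma::mat& X, const arma::vec& y, int Fmax) {
  const uword p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W(p, Fmax, fill::zeros), P(p, Fmax, fill::zeros);
  vec q(Fmax, fill::zeros);
  int a = 0;
  for (; a < Fmax; ++a) {
    if (norm(Xc, "fro") < PLS_TOL) break;
    vec w = Xc.t() * yc;
    double nw = norm(w);
    if (nw < PLS_TOL) break;
    w /= nw;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < PLS_TOL) break;
    vec pv = Xc.t() * t / tt;
    double qv = dot(yc, t) / tt;
    Xc -= t * pv.t();
    yc -= qv * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qv;
  }
  vec coef(p, fill::zeros);
  if (a > 0) {
    mat Wa = W.cols(0, a - 1), Pa = P.cols(0, a - 1);
    coef = Wa * solve(Pa.t() * Wa, q.subvec(0, a - 1));
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = coef,
                            Rcpp::Named("x_mean") = xm.t(),
                            Rcpp::Named("y_mean") = ym,
                            Rcpp::Named("n_components") = a);
}

// Symmetric matrix of LOOCV SECV scores for every unordered wavelength pair
// under the model y ~ 1 + x_i + x_k, using the hat-matrix leave-one-out
// identity (loo residual = residual / (1 - leverage)). Each pair is computed
// once and mirrored. Non-identifiable pairs (collinear/constant columns or a
// leverage at 1) get +Inf; the diagonal is NaN.
// [[Rcpp::export]]
arma::mat pair_secv_cpp(const arma::mat& X, const arma::vec& y) {
  const uword n = X.n_rows, N = X.n_cols;
  rowvec xm = mean(X, 0);
  mat Xc = X.each_row() - xm;
  vec yc = y - mean(y);
  vec css = trans(sum(square(Xc), 0));  // per-column sum of squares
  vec cxy = Xc.t() * yc;                // per-column cross-product with y
  mat S(N, N);
  S.fill(datum::inf);
  S.diag().fill(datum::nan);
  const double inv_n = 1.0 / static_cast<double>(n);
  for (uword i = 0; i + 1 < N; ++i) {
    const double* u = Xc.colptr(i);
    const double Suu = css(i), Suy = cxy(i);
    for (uword k = i + 1; k < N; ++k) {
      const double* v = Xc.colptr(k);
      const double Svv = css(k), Svy = cxy(k);
      double Suv = 0.0;
      for (uword j = 0; j < n; ++j) Suv += u[j] * v[j];
      const double det = Suu * Svv - Suv * Suv;
      if (!(det > 1e-12 * Suu * Svv)) continue;  // rank-deficient pair
      const double b1 = (Svv * Suy - Suv * Svy) / det;
      const double b2 = (Suu * Svy - Suv * Suy) / det;
      double press = 0.0;
      bool ok = true;
      for (uword j = 0; j < n; ++j) {
        const double uj = u[j], vj = v[j];
        const double e = yc(j) - b1 * uj - b2 * vj;
        const double h =
            inv_n + (Svv * uj * uj - 2.0 * Suv * uj * vj + Suu * vj * vj) / det;
        if (h >= 1.0 - 1e-10) { ok = false; break; }
        const double r = e / (1.0 - h);
        press += r * r;
      }
      if (!ok) continue;
      const double s = std::sqrt(press * inv_n);
      S(i, k) = s;
      S(k, i) = s;
    }
  }
  return S;
}
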