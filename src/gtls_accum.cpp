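// Per-pair accumulations of the GTLS registration phase. The normal-equation
// solve, iteration logic and all error reporting stay on the R side; these
// kernels only sum the small per-pair contributions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat33 row_sym3(const NumericMatrix &M, int i) {
  arma::mat33 out;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) out(r, c) = M(i, c * 3 + r);
  return out;
}

static inline bool inv_checked(const arma::mat33 &M, arma::mat33 &W) {
  const double a = M(0,0), b = M(0,1), c = M(0,2);
  const double d = M(1,1), e = M(1,2), f = M(2,2);
  const double A = d*f - e*e, B = c*e - b*f, C = b*e - c*d;
  const double det = a*A + b*B + c*C;
  const double scale = (a + d + f) / 3.0;
  if (!(det > 1e-12 * scale * scale * scale)) return false;
  W(0,0) = A;          W(0,1) = B;          W(0,2) = C;
  W(1,0) = B;          W(1,1) = a*f - c*c;  W(1,2) = c*b - a*e;
  W(2,0) = C;          W(2,1) = c*b - a*e;  W(2,2) = a*d - b*b;
  W /= det;
  return true;
}

static inline arma::mat33 skew3(const arma::vec3 &v) {
  arma::mat33 S(arma::fill::zeros);
  S(0,1) = -v(2); S(0,2) = v(1);
  S(1,0) = v(2);  S(1,2) = -v(0);
  S(2,0) = -v(1); S(2,1) = v(0);
  return S;
}

// Accumulate A = J' M^-1 J and b = J' M^-1 F0 over pairs, exploiting the
// block-diagonal covariance. Returns bad_pair > 0 (1-based) when a combined
// covariance is numerically singular.
// [[Rcpp::export]]
List cpp_gtls_accumulate(NumericMatrix X, NumericMatrix Y,
                         NumericMatrix Mx, NumericMatrix My,
                         NumericMatrix Rmat, NumericVector tvec,
                         bool rotation_only) {
  const int n = X.nrow();
  arma::mat33 R;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R(r, c) = Rmat(r, c);
  const arma::vec3 t = {tvec[0], tvec[1], tvec[2]};
  const int p = rotation_only ? 3 : 6;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const arma::vec3 x = {X(i,0), X(i,1), X(i,2)};
    const arma::vec3 y = {Y(i,0), Y(i,1), Y(i,2)};
    const arma::vec3 u = R * x;
    const arma::vec3 F0 = y - u - t;
    const arma::mat33 M = R * row_sym3(Mx, i) * R.t() + row_sym3(My, i);
    arma::mat33 W;
    if (!inv_checked(M, W))
      return List::create(_["bad_pair"] = i + 1);
    const arma::mat33 S = skew3(u);
    const arma::mat33 WS = W * S;
    const arma::vec3 WF = W * F0;
    // J_i = [S | -I]; A += J' W J, b += J' W F0 with S' = -S
    A.submat(0, 0, 2, 2) -= S * WS;
    b.subvec(0, 2) -= S * WF;
    if (!rotation_only) {
      A.submat(0, 3, 2, 5) -= WS.t();   // -S'W(-I) = S W = -(WS)'
      A.submat(3, 3, 5, 5) += W;
      b.subvec(3, 5) -= WF;
    }
  }
  if (!rotation_only) {
    // fill the lower-left block from symmetry of A
    A.submat(3, 0, 5, 2) = A.submat(0, 3, 2, 5).t();
  }
  return List::create(_["A"] = A, _["b"] = b, _["bad_pair"] = 0);
}

// Sum of squared Mahalanobis residuals under the combined covariances
// (optionally with an extra isotropic sigma2 on the target side), and the
// per-pair values. Used by the GTLS cost and the chi-square outlier test.
// [[Rcpp::export]]
List cpp_sqr_mahalanobis(NumericMatrix X, NumericMatrix Y,
                         NumericMatrix Mx, NumericMatrix My,
                         NumericMatrix Rmat, NumericVector tvec,
                         double sigma2) {
  const int n = X.nrow();
  arma::mat33 R;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R(r, c) = Rmat(r, c);
  const arma::vec3 t = {tvec[0], tvec[1], tvec[2]};
  NumericVector d2(n);
  for (int i = 0; i < n; ++i) {
    const arma::vec3 x = {X(i,0), X(i,1), X(i,2)};
    const arma::vec3 y = {Y(i,0), Y(i,1), Y(i,2)};
    const arma::vec3 F0 = y - R * x - t;
    arma::mat33 M = R * row_sym3(Mx, i) * R.t() + row_sym3(My, i);
    M(0,0) += sigma2; M(1,1) += sigma2; M(2,2) += sigma2;
    arma::mat33 W;
    if (!inv_checked(M, W))
      return List::create(_["bad_pair"] = i + 1);
    d2[i] = arma::dot(F0, W * F0);
  }
  return List::create(_["d2"] = d2, _["bad_pair"] = 0);
}
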