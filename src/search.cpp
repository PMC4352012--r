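// Correspondence-phase hot path: per-datum most-likely point computation and
// the PD-tree search with ellipsoid/sphere node bounds. Everything here is
// mirrored by plain-R oracles in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::vec;
using arma::mat;

static const int CRIT_MLP = 0, CRIT_MD = 1, CRIT_CP = 2;
static const int BOUND_ELLIPSOID = 0, BOUND_SPHERE = 1;

static inline arma::mat33 sym3_from_row(const NumericMatrix &M, int i) {
  arma::mat33 out;
  // rows store as.vector(3x3) in R column-major order
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      out(r, c) = M(i, c * 3 + r);
  return out;
}

static inline double det3(const arma::mat33 &M) {
  return M(0,0) * (M(1,1)*M(2,2) - M(1,2)*M(2,1))
       - M(0,1) * (M(1,0)*M(2,2) - M(1,2)*M(2,0))
       + M(0,2) * (M(1,0)*M(2,1) - M(1,1)*M(2,0));
}

// adjugate inverse of a symmetric 3x3 (matches the R-side inv3_sym)
static inline arma::mat33 inv_sym3(const arma::mat33 &M) {
  const double a = M(0,0), b = M(0,1), c = M(0,2);
  const double d = M(1,1), e = M(1,2), f = M(2,2);
  const double A = d*f - e*e, B = c*e - b*f, C = b*e - c*d;
  const double det = a*A + b*B + c*C;
  arma::mat33 out;
  out(0,0) = A;          out(0,1) = B;          out(0,2) = C;
  out(1,0) = B;          out(1,1) = a*f - c*c;  out(1,2) = c*b - a*e;
  out(2,0) = C;          out(2,1) = c*b - a*e;  out(2,2) = a*d - b*b;
  return out / det;
}

static inline double quad3(const arma::mat33 &W, const arma::vec3 &r) {
  return arma::dot(r, W * r);
}

// Minimize (z - x)' W (z - x) over the closed triangle (v0, v1, v2).
// Exact for this convex QP: interior stationary point if feasible,
// otherwise the minimum lies on one of the three edges.
static void tri_best_point(const arma::vec3 &v0, const arma::vec3 &v1,
                           const arma::vec3 &v2, const arma::vec3 &x,
                           const arma::mat33 &W,
                           arma::vec3 &z_out, double &q_out) {
  const arma::vec3 e0 = v1 - v0, e1 = v2 - v0;
  const arma::vec3 We0 = W * e0, We1 = W * e1;
  const double g00 = arma::dot(e0, We0), g01 = arma::dot(e0, We1),
               g11 = arma::dot(e1, We1);
  const arma::vec3 d0 = x - v0;
  const double b0 = arma::dot(We0, d0), b1 = arma::dot(We1, d0);
  const double det = g00 * g11 - g01 * g01;
  if (det > 1e-14 * std::max(1.0, g00 * g11)) {
    const double s = (g11 * b0 - g01 * b1) / det;
    const double t = (g00 * b1 - g01 * b0) / det;
    if (s >= 0.0 && t >= 0.0 && s + t <= 1.0) {
      z_out = v0 + s * e0 + t * e1;
      q_out = quad3(W, z_out - x);
      return;
    }
  }
  double best = std::numeric_limits<double>::infinity();
  arma::vec3 bz;
  const arma::vec3 A[3] = { v0, v0, v1 };
  const arma::vec3 B[3] = { v1, v2, v2 };
  for (int k = 0; k < 3; ++k) {
    const arma::vec3 dir = B[k] - A[k];
    const arma::vec3 Wd = W * dir;
    const double den = arma::dot(dir, Wd);
    double u = 0.0;
    if (den > 1e-300) u = arma::dot(Wd, x - A[k]) / den;
    if (u < 0.0) u = 0.0; else if (u > 1.0) u = 1.0;
    const arma::vec3 z = A[k] + u * dir;
    const double q = quad3(W, z - x);
    if (q < best) { best = q; bz = z; }
  }
  z_out = bz;
  q_out = best;
}

struct DatumSet {
  int kind;                 // 0 point, 1 triangle
  NumericMatrix geom;       // n x 3 or n x 9 (v1, v2, v3 coordinate triples)
  NumericMatrix My;         // n x 9 total target covariance (My + MSy)
  int n() const { return geom.nrow(); }
  void vertices(int i, arma::vec3 &v0, arma::vec3 &v1, arma::vec3 &v2) const {
    for (int k = 0; k < 3; ++k) {
      v0(k) = geom(i, k);
      v1(k) = geom(i, 3 + k);
      v2(k) = geom(i, 6 + k);
    }
  }
};

// Evaluate the best point and match error on datum i for the given criterion.
static void eval_datum(const DatumSet &D, int i, int criterion,
                       const arma::vec3 &c, const arma::mat33 &Mxr,
                       arma::vec3 &y_out, double &err_out) {
  if (criterion == CRIT_CP) {
    if (D.kind == 0) {
      arma::vec3 p;
      for (int k = 0; k < 3; ++k) p(k) = D.geom(i, k);
      y_out = p;
      err_out = arma::dot(p - c, p - c);
    } else {
      arma::vec3 v0, v1, v2;
      D.vertices(i, v0, v1, v2);
      arma::mat33 I = arma::eye(3, 3);
      tri_best_point(v0, v1, v2, c, I, y_out, err_out);
    }
    return;
  }
  const arma::mat33 M = Mxr + sym3_from_row(D.My, i);
  const arma::mat33 W = inv_sym3(M);
  if (D.kind == 0) {
    arma::vec3 p;
    for (int k = 0; k < 3; ++k) p(k) = D.geom(i, k);
    y_out = p;
    err_out = quad3(W, p - c);
  } else {
    arma::vec3 v0, v1, v2;
    D.vertices(i, v0, v1, v2);
    tri_best_point(v0, v1, v2, c, W, y_out, err_out);
  }
  if (criterion == CRIT_MLP) err_out += std::log(det3(M));
}

struct TreeArrays {
  NumericMatrix frameR;     // K x 9, columns of the local frame (world coords)
  NumericMatrix origin;     // K x 3
  NumericMatrix bmin, bmax; // K x 3 box extents in the local frame
  IntegerVector left, right;    // 1-based child node indices, 0 = leaf
  IntegerVector dstart, dend;   // 1-based inclusive range into perm (leaves)
  IntegerVector perm;           // 1-based datum indices
  NumericMatrix lam_min;    // K x 3 per-rank minima of target eigenvalues
  NumericVector lam_max;    // K, max target eigenvalue in node
};

// Sound node prune test. Returns true when the node box may contain a target
// point whose match error is below E_best. For spheres the exact
// closest-point-on-box test is used; for ellipsoids, the box of the
// ellipsoid's support extents along the node axes (conservative: no false
// negatives).
static bool node_may_contain(const TreeArrays &T, int j, int criterion,
                             int bound, const arma::vec3 &c,
                             const arma::mat33 &Mxr, const arma::vec3 &lamx,
                             double lamx_max, double E_best) {
  double rhs = E_best;
  if (criterion == CRIT_MLP) {
    double logmin = 0.0;
    for (int k = 0; k < 3; ++k) logmin += std::log(lamx(k) + T.lam_min(j, k));
    rhs = E_best - logmin;
  }
  if (!(rhs > 0.0)) return false;
  // local-frame center
  arma::mat33 Fr;
  for (int col = 0; col < 3; ++col)
    for (int row = 0; row < 3; ++row)
      Fr(row, col) = T.frameR(j, col * 3 + row);
  const arma::vec3 cl = Fr.t() * (c - arma::vec3({T.origin(j,0), T.origin(j,1), T.origin(j,2)}));
  const bool spherical = (criterion == CRIT_CP) || (bound == BOUND_SPHERE);
  if (spherical) {
    const double r2 = (criterion == CRIT_CP) ? rhs : rhs * (lamx_max + T.lam_max[j]);
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double e = 0.0;
      if (cl(k) < T.bmin(j, k)) e = T.bmin(j, k) - cl(k);
      else if (cl(k) > T.bmax(j, k)) e = cl(k) - T.bmax(j, k);
      d2 += e * e;
    }
    return d2 <= r2;
  }
  arma::mat33 Msub = Mxr;
  Msub(0,0) += T.lam_max[j]; Msub(1,1) += T.lam_max[j]; Msub(2,2) += T.lam_max[j];
  for (int k = 0; k < 3; ++k) {
    const arma::vec3 a = Fr.col(k);
    const double h = std::sqrt(rhs * arma::dot(a, Msub * a));
    if (cl(k) - h > T.bmax(j, k) || cl(k) + h < T.bmin(j, k)) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_find_matches(int kind, NumericMatrix geom, NumericMatrix Mytot,
                      NumericMatrix frameR, NumericMatrix origin,
                      NumericMatrix bmin, NumericMatrix bmax,
                      IntegerVector left, IntegerVector right,
                      IntegerVector dstart, IntegerVector dend,
                      IntegerVector perm,
                      NumericMatrix lam_min, NumericVector lam_max,
                      NumericMatrix X, NumericMatrix MxEff,
                      NumericMatrix Rmat, NumericVector tvec,
                      int criterion, int bound, IntegerVector prev_idx) {
  DatumSet D{kind, geom, Mytot};
  TreeArrays T{frameR, origin, bmin, bmax, left, right, dstart, dend,
               perm, lam_min, lam_max};
  const int m = X.nrow();
  arma::mat33 R;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R(r, c) = Rmat(r, c);
  const arma::vec3 t = {tvec[0], tvec[1], tvec[2]};

  NumericMatrix Yout(m, 3);
  IntegerVector idx_out(m);
  NumericVector err_out(m);
  IntegerVector nodes_tested(m), datums_eval(m);
  std::vector<int> stack;
  stack.reserve(64);

  for (int q = 0; q < m; ++q) {
    arma::vec3 x = {X(q,0), X(q,1), X(q,2)};
    const arma::mat33 Mx = sym3_from_row(MxEff, q);
    const arma::mat33 Mxr = R * Mx * R.t();
    arma::vec3 lamx(arma::fill::zeros);
    double lamx_max = 0.0;
    if (criterion != CRIT_CP) {
      arma::vec ev;
      arma::eig_sym(ev, arma::symmatu(Mx));   // ascending, rotation-invariant
      lamx = ev;
      lamx_max = ev(2);
    }
    const arma::vec3 c = R * x + t;

    double best_err = std::numeric_limits<double>::infinity();
    int best_idx = -1;
    arma::vec3 best_y(arma::fill::zeros);
    int ntest = 0, neval = 0;

    if (prev_idx[q] > 0) {
      const int i = prev_idx[q] - 1;
      eval_datum(D, i, criterion, c, Mxr, best_y, best_err);
      best_idx = i;
      ++neval;
    }

    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      const int j = stack.back();
      stack.pop_back();
      ++ntest;
      if (!node_may_contain(T, j, criterion, bound, c, Mxr, lamx,
                            lamx_max, best_err))
        continue;
      if (left[j] == 0) {                  // leaf
        for (int s = dstart[j] - 1; s <= dend[j] - 1; ++s) {
          const int i = perm[s] - 1;
          arma::vec3 y;
          double e;
          eval_datum(D, i, criterion, c, Mxr, y, e);
          ++neval;
          if (e < best_err || (e == best_err && i < best_idx)) {
            best_err = e;
            best_idx = i;
            best_y = y;
          }
        }
      } else {
        stack.push_back(right[j] - 1);
        stack.push_back(left[j] - 1);
      }
    }
    Yout(q,0) = best_y(0); Yout(q,1) = best_y(1); Yout(q,2) = best_y(2);
    idx_out[q] = best_idx + 1;
    err_out[q] = best_err;
    nodes_tested[q] = ntest;
    datums_eval[q] = neval;
  }
  return List::create(_["y"] = Yout, _["idx"] = idx_out, _["err"] = err_out,
                      _["nodes_tested"] = nodes_tested,
                      _["datums_evaluated"] = datums_eval);
}

// Exhaustive search over all datums (no tree): oracle route for validating
// the pruned search, and the naive baseline for operation-count comparisons.
// [[Rcpp::export]]
List cpp_exhaustive_match(int kind, NumericMatrix geom, NumericMatrix Mytot,
                          NumericMatrix X, NumericMatrix MxEff,
                          NumericMatrix Rmat, NumericVector tvec,
                          int criterion) {
  DatumSet D{kind, geom, Mytot};
  const int m = X.nrow(), n = D.n();
  arma::mat33 R;
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R(r, c) = Rmat(r, c);
  const arma::vec3 t = {tvec[0], tvec[1], tvec[2]};
  NumericMatrix Yout(m, 3);
  IntegerVector idx_out(m);
  NumericVector err_out(m);
  for (int q = 0; q < m; ++q) {
    arma::vec3 x = {X(q,0), X(q,1), X(q,2)};
    const arma::mat33 Mx = sym3_from_row(MxEff, q);
    const arma::mat33 Mxr = R * Mx * R.t();
    const arma::vec3 c = R * x + t;
    double best_err = std::numeric_limits<double>::infinity();
    int best_idx = -1;
    arma::vec3 best_y(arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      arma::vec3 y;
      double e;
      eval_datum(D, i, criterion, c, Mxr, y, e);
      if (e < best_err || (e == best_err && i < best_idx)) {
        best_err = e; best_idx = i; best_y = y;
      }
    }
    Yout(q,0) = best_y(0); Yout(q,1) = best_y(1); Yout(q,2) = best_y(2);
    idx_out[q] = best_idx + 1;
    err_out[q] = best_err;
  }
  return List::create(_["y"] = Yout, _["idx"] = idx_out, _["err"] = err_out);
}

// Best point on a single datum under the quadratic form W (or Euclidean).
// [[Rcpp::export]]
List cpp_datum_best_point(int kind, NumericVector geom_row,
                          NumericVector x_transformed, NumericMatrix W,
                          bool euclidean) {
  arma::vec3 c = {x_transformed[0], x_transformed[1], x_transformed[2]};
  arma::mat33 Wm;
  if (euclidean) {
    Wm = arma::eye(3, 3);
  } else {
    for (int ccol = 0; ccol < 3; ++ccol)
      for (int r = 0; r < 3; ++r) Wm(r, ccol) = W(r, ccol);
  }
  arma::vec3 z;
  double q;
  if (kind == 0) {
    z = {geom_row[0], geom_row[1], geom_row[2]};
    q = quad3(Wm, z - c);
  } else {
    arma::vec3 v0 = {geom_row[0], geom_row[1], geom_row[2]};
    arma::vec3 v1 = {geom_row[3], geom_row[4], geom_row[5]};
    arma::vec3 v2 = {geom_row[6], geom_row[7], geom_row[8]};
    tri_best_point(v0, v1, v2, c, Wm, z, q);
  }
  return List::create(_["y"] = NumericVector::create(z(0), z(1), z(2)),
                      _["quad"] = q);
}
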