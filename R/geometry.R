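#' Rigid-body transforms and 3D rotation utilities
#'
#' A rigid transform is stored as a list with a 3x3 rotation matrix `R`
#' (dimensionless, `R'R = I`, `det(R) = +1`) and a translation 3-vector `t`
#' (mm), applied to a point as `y = R x + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' T1 <- rigid_transform(rodrigues(c(0, 0, pi / 2)), c(1, 2, 3))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation matrix (orthonormal, det +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param T_ a `rigid_transform`.
#' @param x a 3-vector or an n x 3 matrix of points (mm).
#' @export
apply_transform <- function(T_, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(T_$R), 2, T_$t, "+")
  } else {
    drop(T_$R %*% x) + T_$t
  }
}

#' @rdname rigid_transform
#' @param A,B rigid transforms; `compose_transform(A, B)` applies B first.
#' @export
compose_transform <- function(A, B) {
  rigid_transform(A$R %*% B$R, drop(A$R %*% B$t) + A$t)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(T_) {
  rigid_transform(t(T_$R), drop(-t(T_$R) %*% T_$t))
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' Returns the antisymmetric matrix `S` such that `S %*% w` equals the cross
#' product `v x w`. This is the linearization of an incremental rotation:
#' a small rotation by axis-angle `da` acts as `I + skew(da)`.
#'
#' @param v a numeric 3-vector.
#' @return A 3x3 antisymmetric matrix.
#' @export
skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rodrigues rotation formula
#'
#' Converts an axis-angle 3-vector into a rotation matrix: the rotation axis
#' is `alpha / |alpha|` and the rotation angle is `|alpha|` radians.
#' `rodrigues(c(0,0,0))` is the identity. The result always satisfies the
#' rotation-matrix invariants exactly (up to floating point), which is why
#' the Gauss-Newton solver uses it instead of the skew approximation when
#' applying incremental rotations.
#'
#' @param alpha axis-angle 3-vector (radians).
#' @return A 3x3 rotation matrix.
#' @export
rodrigues <- function(alpha) {
  alpha <- as.numeric(alpha)
  th <- sqrt(sum(alpha^2))
  K <- skew(alpha)
  if (th < 1e-8) {
    # series expansion; exact to machine precision at these angles
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  Kn <- K / th
  diag(3) + sin(th) * Kn + (1 - cos(th)) * (Kn %*% Kn)
}

#' Axis-angle logarithm of a rotation matrix
#'
#' Inverse of [rodrigues()]: extracts the axis-angle vector with norm in
#' `[0, pi]`. Uses an atan2-based angle so the extraction is stable near 0
#' and near pi (half-turns).
#'
#' @param R a 3x3 rotation matrix.
#' @return Axis-angle 3-vector (radians), `rodrigues(rotation_log(R)) == R`.
#' @export
rotation_log <- function(R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation_log: input is not a rotation matrix")
  sv <- 0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(sv^2))                      # sin(theta)
  cth <- (sum(diag(R)) - 1) / 2             # cos(theta)
  cth <- min(1, max(-1, cth))
  th <- atan2(s, cth)
  if (th < 1e-8) return(sv)                 # sv ~ theta * axis already
  if (th < pi - 1e-4) return(sv / s * th)
  # near pi: axis from the symmetric part, signs fixed from the largest entry
  u <- sqrt(pmax(0, (diag(R) - cth) / (1 - cth)))
  i <- which.max(u)
  for (j in seq_len(3)[-i]) {
    sgn <- sign(R[i, j] + R[j, i])
    if (sgn != 0) u[j] <- sgn * u[j]
  }
  u <- u / sqrt(sum(u^2))
  if (s > 1e-12 && sum(u * sv) < 0) u <- -u
  u * th
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly over SO(3) by normalizing a 4-vector of iid
#' standard Gaussians into a unit quaternion. Uses R's global RNG stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Random covariance with prescribed eigenvalues
#'
#' Builds `V diag(eigenvalues) V'` where `V` is a uniformly random rotation,
#' i.e. a covariance of fixed shape (eigenvalue magnitudes) and uniformly
#' random orientation. This is how the synthetic benchmarks draw anisotropic
#' per-point noise models.
#'
#' @param eigenvalues non-negative 3-vector of eigenvalues (mm^2).
#' @return A symmetric positive semidefinite 3x3 matrix.
#' @export
random_covariance <- function(eigenvalues) {
  eigenvalues <- as.numeric(eigenvalues)
  stopifnot(length(eigenvalues) == 3)
  if (any(eigenvalues < 0)) stop("random_covariance: negative eigenvalue")
  V <- random_rotation()
  V %*% (eigenvalues * t(V))
}

#' Surface-oriented covariance
#'
#' Covariance with variance `sigma_normal^2` along a unit surface normal and
#' `sigma_parallel^2` in the two tangential directions. Used both to model
#' the local surface patch around a sampled point (large tangential
#' variance) and to generate surface-conditioned measurement noise.
#'
#' @param normal unit 3-vector.
#' @param sigma_normal standard deviation along the normal (mm).
#' @param sigma_parallel standard deviation in the tangent plane (mm).
#' @return A symmetric positive semidefinite 3x3 matrix.
#' @export
surface_covariance <- function(normal, sigma_normal, sigma_parallel) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("surface_covariance: zero normal vector")
  if (abs(nn - 1) > 1e-6) stop("surface_covariance: normal must be unit length")
  P <- tcrossprod(normal)  # projector onto the normal
  sigma_normal^2 * P + sigma_parallel^2 * (diag(3) - P)
}

#' Eigendecomposition of a symmetric positive semidefinite 3x3 matrix
#'
#' Eigenvalues are returned in ascending order with matching eigenvector
#' columns. Ascending order is used consistently throughout the package
#' (the PD-tree log-determinant bound pairs eigenvalues by rank order).
#'
#' @param M symmetric PSD 3x3 matrix.
#' @return List with `values` (ascending 3-vector) and `vectors`
#'   (orthonormal 3x3, column i pairs with value i).
#' @export
eig3_spd <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-9) stop("eig3_spd: matrix is not symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (e$values[3] < -1e-9 * max(1, abs(e$values[1])))
    stop("eig3_spd: matrix is not positive semidefinite")
  list(values = rev(e$values), vectors = e$vectors[, 3:1, drop = FALSE])
}

#' Closed-form inverse of a symmetric 3x3 matrix
#'
#' Adjugate-based inverse, used per point-pair in the GTLS solver and the
#' match-error computations where millions of small inversions occur.
#'
#' @param M symmetric 3x3 matrix.
#' @return The 3x3 inverse.
#' @keywords internal
inv3_sym <- function(M) {
  a <- M[1, 1]; b <- M[1, 2]; c <- M[1, 3]
  d <- M[2, 2]; e <- M[2, 3]; f <- M[3, 3]
  A <- d * f - e * e
  B <- c * e - b * f
  C <- b * e - c * d
  det <- a * A + b * B + c * C
  if (!is.finite(det) || abs(det) < 1e-300)
    stop("inv3_sym: singular matrix")
  matrix(c(A, B, C,
           B, a * f - c * c, c * b - a * e,
           C, c * b - a * e, a * d - b * b), 3, 3) / det
}

# shared validation helper for covariance inputs
check_cov3 <- function(M, what = "covariance") {
  M <- as.matrix(M)
  if (!identical(dim(M), c(3L, 3L))) stop(what, ": must be 3x3")
  if (max(abs(M - t(M))) > 1e-9) stop(what, ": not symmetric")
  M
}
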