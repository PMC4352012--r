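#' @title Alignment of corresponding point sets
#' @description Solvers for the registration phase: the closed-form
#'   least-squares solution under isotropic noise and the Gauss-Newton
#'   generalized total-least-squares (GTLS) solution under per-pair
#'   anisotropic covariances.
#' @name gtls
NULL

# Coerce covariance input (3x3 matrix recycled, list of 3x3, or 3x3xn array)
# to a 3x3xn array.
as_cov_array <- function(M, n, what = "covariances") {
  if (is.list(M)) {
    stopifnot(length(M) == n)
    out <- array(0, c(3, 3, n))
    for (i in seq_len(n)) out[, , i] <- check_cov3(M[[i]], what)
    return(out)
  }
  if (is.array(M) && length(dim(M)) == 3) {
    if (!all(dim(M)[1:2] == 3) || dim(M)[3] != n)
      stop(what, ": array must be 3x3x", n)
    return(M)
  }
  M <- check_cov3(M, what)
  array(M, c(3, 3, n))
}

# flatten a 3x3xn array into n x 9 rows (column-major per slice), the
# layout shared with the C++ kernels
cov_rows <- function(arr) t(matrix(arr, 9, dim(arr)[3]))

check_corresponding <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3, ncol(Y) == 3)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal numbers of points")
  if (nrow(X) < 3) stop("at least 3 corresponding pairs are required")
  list(X = X, Y = Y)
}

#' Closed-form rigid alignment of corresponding points (isotropic noise)
#'
#' Minimizes the sum of squared distances `sum || y_i - R x_i - t ||^2`
#' over rigid transforms via the SVD of the centered cross-covariance,
#' with a reflection correction enforcing `det(R) = +1`. This is the
#' registration step of standard ICP and is optimal when the point noise
#' is isotropic and identical across pairs.
#'
#' @param X,Y n x 3 matrices of corresponding source and target points (mm).
#' @param rotation_only if `TRUE`, estimate rotation about the origin with
#'   translation fixed at zero (cross-covariance taken about the origin).
#' @return A [rigid_transform()].
#' @export
register_corresponding_isotropic <- function(X, Y, rotation_only = FALSE) {
  s <- check_corresponding(X, Y); X <- s$X; Y <- s$Y
  if (rotation_only) {
    H <- crossprod(X, Y)
    cx <- c(0, 0, 0); cy <- c(0, 0, 0)
  } else {
    cx <- colMeans(X); cy <- colMeans(Y)
    H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  }
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate point configuration (rank < 2)")
  D <- diag(c(1, 1, det(sv$v %*% t(sv$u))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- if (rotation_only) c(0, 0, 0) else cy - drop(R %*% cx)
  rigid_transform(R, t)
}

#' GTLS cost: sum of squared Mahalanobis distances
#'
#' Evaluates `sum_i (y_i - R x_i - t)' (R Mx_i R' + My_i)^{-1}
#' (y_i - R x_i - t)`, the objective minimized by the GTLS registration
#' phase (the log-determinant term of the match error is dropped there
#' because the matches, hence target covariances, are fixed).
#'
#' @inheritParams register_corresponding_isotropic
#' @param Mx,My source/target covariances: a single 3x3 matrix (recycled),
#'   a list of n matrices, or a 3x3xn array (mm^2).
#' @param T_ a [rigid_transform()].
#' @return Non-negative scalar; zero iff all residuals are zero.
#' @export
gtls_cost <- function(X, Y, Mx, My, T_) {
  s <- check_corresponding(X, Y); X <- s$X; Y <- s$Y
  n <- nrow(X)
  Mx <- as_cov_array(Mx, n, "Mx"); My <- as_cov_array(My, n, "My")
  res <- cpp_sqr_mahalanobis(X, Y, cov_rows(Mx), cov_rows(My),
                             T_$R, T_$t, 0)
  if (res$bad_pair > 0)
    stop("singular combined covariance at pair ", res$bad_pair)
  sum(res$d2)
}

#' One Gauss-Newton step of the GTLS alignment
#'
#' Assembles and solves the normal equations `J' M^-1 J dp = -J' M^-1 F0`
#' where `F0` stacks the residuals `y_i - R_k x_i - t_k`, the i-th Jacobian
#' block is `[skew(R_k x_i) | -I]`, and `M` is the block-diagonal combined
#' covariance with blocks `R_k Mx_i R_k' + My_i`. The block structure is
#' exploited directly; the dense 3n x 3n system is never formed.
#'
#' @inheritParams gtls_cost
#' @param rotation_only if `TRUE`, solve the 3x3 rotation-only system.
#' @return The parameter update `dp`: `c(dalpha, dt)` (radians, mm), or
#'   just `dalpha` when `rotation_only`.
#' @export
gn_step <- function(X, Y, Mx, My, T_, rotation_only = FALSE) {
  s <- check_corresponding(X, Y); X <- s$X; Y <- s$Y
  n <- nrow(X)
  Mx <- as_cov_array(Mx, n, "Mx"); My <- as_cov_array(My, n, "My")
  gn_step_rows(X, Y, cov_rows(Mx), cov_rows(My), T_, rotation_only)
}

# accumulation kernel + solve, on pre-flattened covariance rows
gn_step_rows <- function(X, Y, Mx_rows, My_rows, T_, rotation_only = FALSE) {
  acc <- cpp_gtls_accumulate(X, Y, Mx_rows, My_rows, T_$R, T_$t,
                             rotation_only)
  if (acc$bad_pair > 0)
    stop("singular combined covariance at pair ", acc$bad_pair)
  p <- if (rotation_only) 3L else 6L
  qrA <- qr(acc$A)
  if (qrA$rank < p) stop("degenerate geometry: normal matrix is singular")
  drop(solve(qrA, -acc$b))
}

#' Gauss-Newton GTLS registration of corresponding point sets
#'
#' Iterates [gn_step()], updating `R <- rodrigues(dalpha) %*% R` and
#' `t <- t + dt`, until both `|dalpha|` and `|dt|` fall below the
#' thresholds or `max_iter` is reached. The combined covariances are
#' re-rotated at every iteration, so anisotropic source noise is handled
#' correctly under arbitrarily large rotational misalignment. The
#' Rodrigues update keeps the returned rotation exactly orthonormal.
#'
#' No step damping or line search is applied: plain Gauss-Newton with
#' covariance refresh.
#'
#' @inheritParams gtls_cost
#' @param T0 initial [rigid_transform()] (identity by default; no
#'   isotropic initialization is required for stability).
#' @param rot_thresh convergence threshold on `|dalpha|` (degrees).
#' @param trans_thresh convergence threshold on `|dt|` (mm).
#' @param max_iter maximum Gauss-Newton iterations; hitting it flags
#'   non-convergence (`converged = FALSE`) rather than erroring.
#' @param rotation_only if `TRUE`, estimate rotation only with `t = 0`.
#' @return List with `transform` ([rigid_transform()]), `iterations`,
#'   and `converged`.
#' @export
register_corresponding_gtls <- function(X, Y, Mx, My,
                                        T0 = rigid_transform(),
                                        rot_thresh = 1e-4,
                                        trans_thresh = 1e-4,
                                        max_iter = 60,
                                        rotation_only = FALSE) {
  stopifnot(rot_thresh > 0, trans_thresh > 0, max_iter >= 1)
  s <- check_corresponding(X, Y); X <- s$X; Y <- s$Y
  n <- nrow(X)
  Mx <- as_cov_array(Mx, n, "Mx"); My <- as_cov_array(My, n, "My")
  rot_thresh_rad <- rot_thresh * pi / 180
  Mx_rows <- cov_rows(Mx); My_rows <- cov_rows(My)
  R <- T0$R; tt <- T0$t
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    Tk <- rigid_transform(R, tt)
    dp <- gn_step_rows(X, Y, Mx_rows, My_rows, Tk,
                       rotation_only = rotation_only)
    dalpha <- dp[1:3]
    dt <- if (rotation_only) c(0, 0, 0) else dp[4:6]
    R <- rodrigues(dalpha) %*% R
    tt <- tt + dt
    iter <- iter + 1L
    if (sqrt(sum(dalpha^2)) <= rot_thresh_rad &&
        sqrt(sum(dt^2)) <= trans_thresh) {
      converged <- TRUE
      break
    }
  }
  # re-orthonormalize against accumulated round-off before returning
  sv <- svd(R)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  list(transform = rigid_transform(R, tt),
       iterations = iter,
       converged = converged)
}

#' @rdname register_corresponding_gtls
#' @details `register_gtls_rotation_only()` is the rotation-only variant
#'   (translation fixed at zero), used in the rotation-estimation
#'   benchmark.
#' @param R0 initial rotation matrix.
#' @export
register_gtls_rotation_only <- function(X, Y, Mx, My, R0 = diag(3),
                                        rot_thresh = 1e-4,
                                        max_iter = 60) {
  register_corresponding_gtls(X, Y, Mx, My,
                              T0 = rigid_transform(R0, c(0, 0, 0)),
                              rot_thresh = rot_thresh,
                              trans_thresh = .Machine$double.xmax,
                              max_iter = max_iter,
                              rotation_only = TRUE)
}
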