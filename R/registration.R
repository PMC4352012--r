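#' Options for the iterative registration loops
#'
#' @param sigma2_max upper bound on the match-uncertainty variance (mm^2);
#'   `Inf` disables the cap. Capping is useful for partial-overlap
#'   registration where the mean squared residual stays large even at the
#'   correct alignment.
#' @param chi2_thresh chi-square outlier threshold on the squared
#'   Mahalanobis match distance (3 degrees of freedom). The default 7.81
#'   is the 0.95 inverse CDF value; a very large value disables outlier
#'   handling.
#' @param outlier_mode `"inflate"` adds the outlier variance terms to the
#'   noise models of flagged matches; `"discard"` removes flagged matches
#'   from the registration phase entirely (recommended for partial
#'   overlap).
#' @param criterion match criterion: `"mlp"` (most-likely point, the full
#'   algorithm), `"md"` (Mahalanobis distance variant) or
#'   `"closest_point"` (CP variant).
#' @param bound PD-tree node bound method.
#' @param rot_thresh,trans_thresh outer-loop termination thresholds on the
#'   change in rotation (degrees) and translation (mm); both must stay
#'   below threshold for two consecutive iterations.
#' @param max_iter maximum outer iterations.
#' @param cycle_tol relative tolerance for the cost-cycling detector.
#' @param inner_rot_thresh,inner_trans_thresh,inner_max_iter convergence
#'   controls of the per-iteration GTLS solve.
#' @return A list of class `imlp_options`.
#' @export
imlp_options <- function(sigma2_max = Inf, chi2_thresh = 7.81,
                         outlier_mode = c("inflate", "discard"),
                         criterion = c("mlp", "md", "closest_point"),
                         bound = c("simple_ellipsoid", "sphere"),
                         rot_thresh = 0.001, trans_thresh = 0.001,
                         max_iter = 100, cycle_tol = 1e-4,
                         inner_rot_thresh = 0.001,
                         inner_trans_thresh = 0.001,
                         inner_max_iter = 60) {
  stopifnot(sigma2_max > 0, chi2_thresh > 0, rot_thresh > 0,
            trans_thresh > 0, max_iter >= 1, cycle_tol >= 0)
  structure(list(sigma2_max = sigma2_max, chi2_thresh = chi2_thresh,
                 outlier_mode = match.arg(outlier_mode),
                 criterion = match.arg(criterion),
                 bound = match.arg(bound),
                 rot_thresh = rot_thresh, trans_thresh = trans_thresh,
                 max_iter = max_iter, cycle_tol = cycle_tol,
                 inner_rot_thresh = inner_rot_thresh,
                 inner_trans_thresh = inner_trans_thresh,
                 inner_max_iter = inner_max_iter),
            class = "imlp_options")
}

#' Source shape with per-point noise models
#'
#' @param points n x 3 matrix of source points (mm).
#' @param Mx per-point measurement-error covariances (3x3 recycled, list,
#'   or 3x3xn array; mm^2). Default zero.
#' @param MSx per-point surface-model covariances, same forms. Default
#'   zero: surface models are meant for point-cloud-to-point-cloud
#'   registration where the local surface around each sample is unmeasured.
#' @return A list of class `imlp_source`.
#' @export
source_shape <- function(points, Mx = NULL, MSx = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  n <- nrow(points)
  zero <- matrix(0, 3, 3)
  structure(list(points = points,
                 Mx = as_cov_array(if (is.null(Mx)) zero else Mx, n, "Mx"),
                 MSx = as_cov_array(if (is.null(MSx)) zero else MSx, n, "MSx"),
                 n = n),
            class = "imlp_source")
}

#' Match-uncertainty variance update
#'
#' The isotropic match-uncertainty variance is the mean squared residual
#' distance over the current inliers, capped at `sigma2_max`. It models
#' residual shape misalignment, preventing the chi-square test from
#' flagging everything as an outlier in early iterations.
#'
#' @param residual_norms vector of residual distances `|y_i - R x_i - t|`
#'   (mm).
#' @param inlier_mask logical vector; only inlier residuals contribute.
#' @param sigma2_max cap (mm^2).
#' @param previous value to keep (with a warning) if no inliers remain.
#' @return Scalar variance (mm^2).
#' @export
update_match_uncertainty <- function(residual_norms, inlier_mask = NULL,
                                     sigma2_max = Inf, previous = 0) {
  if (is.null(inlier_mask)) inlier_mask <- rep(TRUE, length(residual_norms))
  d <- residual_norms[inlier_mask]
  if (length(d) == 0) {
    warning("no inliers: keeping previous match-uncertainty value")
    return(previous)
  }
  min(mean(d^2), sigma2_max)
}

#' Chi-square outlier classification of matches
#'
#' A match is an outlier when its squared Mahalanobis distance, computed
#' with the measurement-error covariances only (`Mx_i` and
#' `My_i + sigma2 I`; the surface model is deliberately excluded, which
#' improves outlier rejection), exceeds `chi2_thresh`.
#'
#' @param X,Y n x 3 matched source and target points (mm).
#' @param Mx,My measurement-error covariances (3x3 recycled, list or
#'   3x3xn array; mm^2).
#' @param sigma2 current match-uncertainty variance (mm^2).
#' @param T_ current [rigid_transform()].
#' @param chi2_thresh threshold (default 7.81 = 0.95 quantile, 3 dof).
#' @return Logical vector, `TRUE` for outliers.
#' @export
classify_outliers <- function(X, Y, Mx, My, sigma2, T_, chi2_thresh = 7.81) {
  s <- check_corresponding(X, Y); X <- s$X; Y <- s$Y
  n <- nrow(X)
  Mx <- as_cov_array(Mx, n, "Mx"); My <- as_cov_array(My, n, "My")
  res <- cpp_sqr_mahalanobis(X, Y, cov_rows(Mx), cov_rows(My),
                             T_$R, T_$t, sigma2)
  if (res$bad_pair > 0)
    stop("singular covariance at pair ", res$bad_pair)
  res$d2 > chi2_thresh
}

#' Outlier variance-inflation terms
#'
#' Flagged outliers receive an added isotropic variance of nine times
#' their squared residual distance (zero for inliers), bringing the
#' outlier match error to about one third of a standard deviation under
#' its inflated noise model and so largely removing its pull on the
#' registration.
#'
#' @inheritParams update_match_uncertainty
#' @param outlier_mask logical vector, `TRUE` for outliers.
#' @return Vector of variances `phi_i` (mm^2).
#' @export
outlier_variances <- function(residual_norms, outlier_mask) {
  ifelse(outlier_mask, 9 * residual_norms^2, 0)
}

#' Cost-cycling detector
#'
#' The noise models change between iterations, so the outer loop has no
#' convergence guarantee and can cycle. A cycle is declared when the
#' registration-phase cost increases twice within a window of four
#' iterations and the cost following the second increase is within a
#' small relative tolerance of the cost following the first.
#'
#' @param cost_history numeric vector of per-iteration registration costs.
#' @param tol relative tolerance.
#' @return Logical.
#' @export
detect_cycle <- function(cost_history, tol = 1e-4) {
  k <- length(cost_history)
  if (k < 4) return(FALSE)
  lo <- max(2L, k - 3L)
  inc <- which(diff(cost_history) > 0) + 1L
  inc <- inc[inc >= lo]
  if (length(inc) < 2) return(FALSE)
  i1 <- inc[length(inc) - 1L]; i2 <- inc[length(inc)]
  abs(cost_history[i2] - cost_history[i1]) <= tol * abs(cost_history[i1])
}

iso9 <- function(s) {
  # n x 9 row for an isotropic covariance s*I in flattened column-major form
  c(s, 0, 0, 0, s, 0, 0, 0, s)
}

add_iso <- function(arr, s) {
  # add s*I to every slice of a 3x3xn array
  if (s == 0) return(arr)
  arr[1, 1, ] <- arr[1, 1, ] + s
  arr[2, 2, ] <- arr[2, 2, ] + s
  arr[3, 3, ] <- arr[3, 3, ] + s
  arr
}

transform_delta <- function(T_new, T_old) {
  dR <- T_new$R %*% t(T_old$R)
  c(rot = norm_vec(rotation_log(dR)) * 180 / pi,
    trans = norm_vec(T_new$t - T_old$t))
}

#' Iterative Most-Likely Point registration
#'
#' Registers a noisy source point set to a target shape (mesh or point
#' cloud) held in a PD tree. Each outer iteration (i) finds, for every
#' source point, the most-likely match on the target under the current
#' transform and effective source covariance `Mx_i + MSx_i + sigma2 I`,
#' (ii) re-estimates the match-uncertainty variance from the inlier
#' residuals, (iii) classifies outliers by the chi-square test and
#' computes their variance-inflation terms, and (iv) updates the transform
#' by GTLS alignment of the matched pairs under the assembled covariances
#' `Mx_i + MSx_i + phi_i/2 I` (source) and `My_i + MSy_i + phi_i/2 I +
#' sigma2 I` (target). The first correspondence pass uses a fully
#' isotropic noise model (the match uncertainty needs correspondences in
#' hand before it can be estimated).
#'
#' Termination: transform changes below threshold for two consecutive
#' iterations, the iteration cap, or detection of a cost cycle (in which
#' case the transform of the last cost-decreasing iteration is returned).
#'
#' The `criterion` option gives the IMLP-MD (`"md"`) and IMLP-CP
#' (`"closest_point"`) variants, which modify only the matching phase.
#'
#' @param source an [source_shape()] (or n x 3 matrix of noiseless points).
#' @param tree a [build_pdtree()] of the target shape with its
#'   measurement and surface covariances.
#' @param options an [imlp_options()] list.
#' @param T0 initial [rigid_transform()].
#' @return A list of class `registration_result`: `transform`,
#'   `iterations`, `terminated_by` (`"converged"`, `"max_iter"` or
#'   `"cycle"`), `sigma2`, `outlier_mask`, and a per-iteration `history`
#'   data frame (cost, sigma2, n_outliers, delta_rot, delta_trans).
#' @export
imlp_register <- function(source, tree, options = imlp_options(),
                          T0 = rigid_transform()) {
  if (!inherits(source, "imlp_source")) source <- source_shape(source)
  stopifnot(inherits(tree, "pdtree"), inherits(options, "imlp_options"))
  X <- source$points
  n <- source$n
  Mx <- source$Mx
  MSx <- source$MSx
  MxS <- Mx + MSx

  T_ <- T0
  sigma2 <- 0
  inlier <- rep(TRUE, n)

  # initial correspondences under a fully isotropic noise model: all three
  # criteria reduce to closest point when every covariance is the identity
  m0 <- find_matches(tree, X, diag(3), T_, criterion = "closest_point")
  idx <- m0$idx
  Y <- m0$y

  history <- vector("list", options$max_iter)
  costs <- numeric(0)
  below_prev <- FALSE
  terminated_by <- "max_iter"
  best_cost <- Inf
  best_T <- T_
  iter <- 0L

  for (k in seq_len(options$max_iter)) {
    if (k > 1L) {
      # Step 5: most-likely correspondences with effective source covariance
      Mx_eff <- add_iso(MxS, sigma2)
      mm <- find_matches(tree, X, Mx_eff, T_, criterion = options$criterion,
                         bound = options$bound, previous_idx = idx)
      idx <- mm$idx
      Y <- mm$y
    }
    My_i <- array(t(tree$My[idx, , drop = FALSE]), c(3, 3, n))
    MSy_i <- array(t(tree$MSy[idx, , drop = FALSE]), c(3, 3, n))

    res_vec <- Y - apply_transform(T_, X)
    d <- sqrt(rowSums(res_vec^2))

    # Step 6: match-uncertainty update over current inliers
    sigma2 <- update_match_uncertainty(d, inlier, options$sigma2_max,
                                       previous = sigma2)

    # Step 7: chi-square outlier test on measurement covariances only
    out_mask <- classify_outliers(X, Y, Mx, My_i, sigma2, T_,
                                  options$chi2_thresh)
    if (all(out_mask))
      stop("imlp_register: all matches classified as outliers (iteration ",
           k, "); check the initial alignment or chi2_thresh")
    inlier <- !out_mask
    phi <- outlier_variances(d, out_mask)

    # Step 8: covariance assembly for the registration phase
    Mx_reg <- MxS
    My_reg <- My_i + MSy_i
    for (d in 1:3) {
      Mx_reg[d, d, ] <- Mx_reg[d, d, ] + phi / 2
      My_reg[d, d, ] <- My_reg[d, d, ] + phi / 2 + sigma2
    }

    keep <- if (options$outlier_mode == "discard") inlier else rep(TRUE, n)
    if (sum(keep) < 3)
      stop("imlp_register: fewer than 3 matches left after discarding outliers")

    # Step 9: GTLS alignment of the (kept) corresponding pairs
    fit <- register_corresponding_gtls(
      X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
      Mx_reg[, , keep, drop = FALSE], My_reg[, , keep, drop = FALSE],
      T0 = T_,
      rot_thresh = options$inner_rot_thresh,
      trans_thresh = options$inner_trans_thresh,
      max_iter = options$inner_max_iter)
    T_new <- fit$transform
    cost <- gtls_cost(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                      Mx_reg[, , keep, drop = FALSE],
                      My_reg[, , keep, drop = FALSE], T_new)

    delta <- transform_delta(T_new, T_)
    T_ <- T_new
    iter <- k
    costs <- c(costs, cost)
    if (cost < best_cost) {
      best_cost <- cost
      best_T <- T_
    }
    history[[k]] <- data.frame(iteration = k, cost = cost, sigma2 = sigma2,
                               n_outliers = sum(out_mask),
                               delta_rot = delta[["rot"]],
                               delta_trans = delta[["trans"]],
                               gtls_iterations = fit$iterations)

    below <- delta[["rot"]] <= options$rot_thresh &&
      delta[["trans"]] <= options$trans_thresh
    if (below && below_prev) {
      terminated_by <- "converged"
      break
    }
    below_prev <- below
    if (detect_cycle(costs, options$cycle_tol)) {
      terminated_by <- "cycle"
      T_ <- best_T
      break
    }
  }

  structure(list(transform = T_, iterations = iter,
                 terminated_by = terminated_by,
                 sigma2 = sigma2, outlier_mask = out_mask,
                 history = do.call(rbind, history[seq_len(iter)])),
            class = "registration_result")
}

#' Standard Iterative Closest Point registration
#'
#' Alternates closest-point matching on the PD tree with the closed-form
#' isotropic alignment, using the same termination rules as
#' [imlp_register()] (thresholds for two consecutive iterations or the
#' iteration cap). No noise models and no outlier handling.
#'
#' @param source n x 3 matrix of source points (or an [source_shape()];
#'   its covariances are ignored).
#' @inheritParams imlp_register
#' @return A `registration_result` (cost column holds the sum of squared
#'   match distances).
#' @export
icp_register <- function(source, tree, options = imlp_options(),
                         T0 = rigid_transform()) {
  if (inherits(source, "imlp_source")) source <- source$points
  X <- as.matrix(source)
  stopifnot(inherits(tree, "pdtree"), nrow(X) >= 3)
  T_ <- T0
  idx <- integer(nrow(X))
  history <- vector("list", options$max_iter)
  below_prev <- FALSE
  terminated_by <- "max_iter"
  iter <- 0L
  for (k in seq_len(options$max_iter)) {
    mm <- find_matches(tree, X, diag(3), T_, criterion = "closest_point",
                       previous_idx = idx)
    idx <- mm$idx
    T_new <- register_corresponding_isotropic(X, mm$y)
    cost <- sum(rowSums((mm$y - apply_transform(T_new, X))^2))
    delta <- transform_delta(T_new, T_)
    T_ <- T_new
    iter <- k
    history[[k]] <- data.frame(iteration = k, cost = cost, sigma2 = 0,
                               n_outliers = 0L,
                               delta_rot = delta[["rot"]],
                               delta_trans = delta[["trans"]],
                               gtls_iterations = 1L)
    below <- delta[["rot"]] <= options$rot_thresh &&
      delta[["trans"]] <= options$trans_thresh
    if (below && below_prev) {
      terminated_by <- "converged"
      break
    }
    below_prev <- below
  }
  structure(list(transform = T_, iterations = iter,
                 terminated_by = terminated_by,
                 sigma2 = 0, outlier_mask = rep(FALSE, nrow(X)),
                 history = do.call(rbind, history[seq_len(iter)])),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Registration:", x$iterations, "iterations, terminated by",
      x$terminated_by, "\n")
  cat("R =\n"); print(round(x$transform$R, 6))
  cat("t =", round(x$transform$t, 6), "\n")
  invisible(x)
}
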