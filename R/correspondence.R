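#' Match-error and Mahalanobis distance between a matched point pair
#'
#' The match error is the negative log of the Gaussian match likelihood (up
#' to an additive constant): `log |R Mx R' + My| + (y - R x - t)'
#' (R Mx R' + My)^{-1} (y - R x - t)`. The log-determinant term must not be
#' dropped when comparing candidate matches, because target noise models
#' may vary in magnitude and orientation across the shape.
#'
#' @param x source point 3-vector (mm).
#' @param y target point 3-vector (mm).
#' @param Mx,My 3x3 noise covariances of the source and target point (mm^2).
#' @param T_ a [rigid_transform()].
#' @return Scalar match error.
#' @export
match_error <- function(x, y, Mx, My, T_) {
  Mx <- check_cov3(Mx, "Mx"); My <- check_cov3(My, "My")
  M <- T_$R %*% Mx %*% t(T_$R) + My
  d <- det(M)
  if (d <= 0) stop("singular combined covariance")
  r <- as.numeric(y) - apply_transform(T_, as.numeric(x))
  log(d) + drop(r %*% inv3_sym(M) %*% r)
}

#' @rdname match_error
#' @details `sqr_mahalanobis()` is the squared Mahalanobis distance alone
#'   (no log-determinant term); under the correspondence and Gaussian noise
#'   assumptions it is chi-square distributed with three degrees of
#'   freedom, which is the basis of the outlier test.
#' @export
sqr_mahalanobis <- function(x, y, Mx, My, T_) {
  Mx <- check_cov3(Mx, "Mx"); My <- check_cov3(My, "My")
  M <- T_$R %*% Mx %*% t(T_$R) + My
  if (det(M) <= 0) stop("singular combined covariance")
  r <- as.numeric(y) - apply_transform(T_, as.numeric(x))
  drop(r %*% inv3_sym(M) %*% r)
}

criterion_code <- function(criterion) {
  switch(match.arg(criterion, c("mlp", "md", "closest_point")),
         mlp = 0L, md = 1L, closest_point = 2L)
}

bound_code <- function(bound) {
  switch(match.arg(bound, c("simple_ellipsoid", "sphere")),
         simple_ellipsoid = 0L, sphere = 1L)
}

#' Best point on a single datum
#'
#' For a point datum, the datum itself. For a triangle datum, the point of
#' the closed triangle minimizing the quadratic form
#' `(z - x')' M_inv (z - x')` (the log-determinant term is constant over a
#' datum and is added by the caller). With `criterion = "closest_point"`
#' the quadratic form is Euclidean.
#'
#' @param datum for a point datum, a 3-vector; for a triangle datum, a
#'   3x3 matrix with one vertex per row (mm).
#' @param x_transformed the transformed source point `R x + t` (mm).
#' @param M_inv inverse of the combined match covariance (1/mm^2).
#' @param criterion `"mlp"`, `"md"` (both use `M_inv`) or
#'   `"closest_point"` (Euclidean).
#' @return List with `y` (best point) and `quad` (quadratic-form value).
#' @export
datum_best_point <- function(datum, x_transformed, M_inv = diag(3),
                             criterion = "mlp") {
  crit <- criterion_code(criterion)
  if (is.matrix(datum)) {
    stopifnot(identical(dim(datum), c(3L, 3L)))
    a <- norm_vec(cross3(datum[2, ] - datum[1, ], datum[3, ] - datum[1, ])) / 2
    if (a < 1e-12) stop("degenerate triangle datum (zero area)")
    row <- as.numeric(t(datum))
    kind <- 1L
  } else {
    row <- c(as.numeric(datum), numeric(6))
    kind <- 0L
  }
  cpp_datum_best_point(kind, row, as.numeric(x_transformed),
                       as.matrix(M_inv), euclidean = (crit == 2L))
}

# cross product and norm helpers
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
norm_vec <- function(v) sqrt(sum(v^2))

tree_kind_code <- function(tree) if (tree$kind == "triangle") 1L else 0L

#' Find the best match on a target shape for each source point
#'
#' Searches the PD tree for the datum and on-datum point minimizing the
#' match criterion over the entire target shape. The search is exact: a
#' node is skipped only when a sound bound proves it cannot contain a
#' better match, so the result always equals exhaustive evaluation.
#' Criteria: `"mlp"` (match error with log term), `"md"` (squared
#' Mahalanobis distance), `"closest_point"` (squared Euclidean distance).
#'
#' `find_match()` handles a single source point and returns a match record;
#' `find_matches()` is the vectorized form used by the registration loops.
#'
#' @param tree a [build_pdtree()] result.
#' @param x source point 3-vector (mm); for `find_matches()`, an m x 3
#'   matrix `X`.
#' @param Mx_effective effective source covariance for matching (3x3; for
#'   `find_matches()` also a list or 3x3xm array; mm^2).
#' @param T_ current [rigid_transform()].
#' @param criterion match criterion, see Details.
#' @param bound node bound method: `"simple_ellipsoid"` (default) or
#'   `"sphere"`.
#' @param previous optional prior match (from a previous iteration) used to
#'   warm-start the search; its datum index seeds the initial best error.
#'   Warm starting never changes the returned optimum, only the number of
#'   nodes visited.
#' @return `find_match()`: list with `y`, `My`, `MSy`, `datum_index`,
#'   `error`, `nodes_tested`, `datums_evaluated`.
#' @export
find_match <- function(tree, x, Mx_effective, T_,
                       criterion = "mlp", bound = "simple_ellipsoid",
                       previous = NULL) {
  prev_idx <- if (is.null(previous)) 0L else as.integer(previous$datum_index)
  res <- find_matches(tree, matrix(as.numeric(x), 1, 3), Mx_effective, T_,
                      criterion = criterion, bound = bound,
                      previous_idx = prev_idx)
  list(y = drop(res$y),
       My = matrix(tree$My[res$idx, ], 3, 3),
       MSy = matrix(tree$MSy[res$idx, ], 3, 3),
       datum_index = res$idx,
       error = res$err,
       nodes_tested = res$nodes_tested,
       datums_evaluated = res$datums_evaluated)
}

#' @rdname find_match
#' @param X m x 3 matrix of source points.
#' @param previous_idx integer vector of prior datum indices (0 = none).
#' @export
find_matches <- function(tree, X, Mx_effective, T_,
                         criterion = "mlp", bound = "simple_ellipsoid",
                         previous_idx = NULL) {
  stopifnot(inherits(tree, "pdtree"))
  X <- as.matrix(X)
  m <- nrow(X)
  Mx_a <- as_cov_array(Mx_effective, m, "Mx_effective")
  Mx_m <- cov_rows(Mx_a)
  if (is.null(previous_idx)) previous_idx <- integer(m)
  res <- cpp_find_matches(tree_kind_code(tree), tree$geom, tree$Mytot,
                          tree$frameR, tree$origin, tree$bmin, tree$bmax,
                          tree$left, tree$right, tree$dstart, tree$dend,
                          tree$perm, tree$lam_min, tree$lam_max,
                          X, Mx_m, T_$R, T_$t,
                          criterion_code(criterion), bound_code(bound),
                          as.integer(previous_idx))
  list(y = res$y, idx = res$idx, err = res$err,
       nodes_tested = res$nodes_tested,
       datums_evaluated = res$datums_evaluated)
}

#' Exhaustive (naive) match search over all datums
#'
#' Loops over every datum of the target with no spatial pruning. This is
#' the reference route for validating the PD-tree search and the baseline
#' for operation-count comparisons; its per-datum evaluations are `n` for
#' every query.
#'
#' @inheritParams find_matches
#' @return List with `y`, `idx`, `err`.
#' @export
exhaustive_matches <- function(tree, X, Mx_effective, T_, criterion = "mlp") {
  stopifnot(inherits(tree, "pdtree"))
  X <- as.matrix(X)
  m <- nrow(X)
  Mx_a <- as_cov_array(Mx_effective, m, "Mx_effective")
  Mx_m <- cov_rows(Mx_a)
  cpp_exhaustive_match(tree_kind_code(tree), tree$geom, tree$Mytot,
                       X, Mx_m, T_$R, T_$t, criterion_code(criterion))
}
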