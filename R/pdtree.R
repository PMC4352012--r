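#' Build a principal-direction (PD) tree over a target shape
#'
#' The PD tree is a hierarchical spatial index whose nodes carry their own
#' local coordinate frame: the node origin is the mean datum position and
#' the axes are the eigenvectors of the covariance of datum positions, with
#' the local x-axis along the direction of greatest variance. Each node
#' stores a minimal local-frame-aligned bounding box containing all member
#' datums (every triangle vertex, not just centroids) and noise-model
#' summaries of the member target covariances: the per-rank minima of their
#' eigenvalues (for the log-determinant lower bound) and the maximum
#' eigenvalue (for the Mahalanobis-term bound).
#'
#' A datum is the smallest element of the target shape: a point of a point
#' cloud or a triangle of a mesh. Splitting is at the median local-x
#' coordinate of the datum centroids (balanced tree) and recursion stops
#' when a node holds at most `leaf_capacity` datums or its box extent falls
#' below `min_extent`.
#'
#' @param target an [imlp_mesh()], a [point_cloud()], or an n x 3 matrix of
#'   points (mm).
#' @param My per-datum measurement-error covariances (single 3x3 matrix,
#'   list, or 3x3xn array; mm^2). Default zero.
#' @param MSy per-datum surface-model covariances, same forms. Default zero.
#' @param leaf_capacity maximum datums per leaf.
#' @param min_extent stop splitting when the largest box extent is below
#'   this size (mm); 0 disables the size criterion.
#' @return An object of class `pdtree`.
#' @export
build_pdtree <- function(target, My = NULL, MSy = NULL,
                         leaf_capacity = 5, min_extent = 0) {
  if (inherits(target, "imlp_mesh")) {
    kind <- "triangle"
    fv <- target$faces
    if (nrow(fv) < 1) stop("build_pdtree: empty mesh")
    V <- target$vertices
    geom <- cbind(V[fv[, 1], , drop = FALSE],
                  V[fv[, 2], , drop = FALSE],
                  V[fv[, 3], , drop = FALSE])
    centroids <- (geom[, 1:3, drop = FALSE] + geom[, 4:6, drop = FALSE] +
                    geom[, 7:9, drop = FALSE]) / 3
  } else {
    kind <- "point"
    P <- if (inherits(target, "imlp_pointcloud")) target$points else as.matrix(target)
    if (is.null(dim(P)) || nrow(P) < 1) stop("build_pdtree: empty input")
    stopifnot(ncol(P) == 3)
    geom <- P
    centroids <- P
  }
  n <- nrow(geom)
  zero <- matrix(0, 3, 3)
  My_a <- as_cov_array(if (is.null(My)) zero else My, n, "My")
  MSy_a <- as_cov_array(if (is.null(MSy)) zero else MSy, n, "MSy")
  # flatten each 3x3 slice column-major into a row (shared with the C++ side)
  My_m <- cov_rows(My_a)
  MSy_m <- cov_rows(MSy_a)
  Mytot_m <- My_m + MSy_m
  eigvals <- t(vapply(seq_len(n), function(i)
    eig3_spd(matrix(Mytot_m[i, ], 3, 3))$values, numeric(3)))

  # --- recursive construction into flat arrays -------------------------
  env <- new.env(parent = emptyenv())
  env$frameR <- list(); env$origin <- list(); env$bmin <- list()
  env$bmax <- list(); env$left <- integer(); env$right <- integer()
  env$dstart <- integer(); env$dend <- integer()
  env$lam_min <- list(); env$lam_max <- numeric()
  env$perm <- integer(); env$K <- 0L

  member_points <- function(idx) {
    if (kind == "point") {
      geom[idx, , drop = FALSE]
    } else {
      rbind(geom[idx, 1:3, drop = FALSE],
            geom[idx, 4:6, drop = FALSE],
            geom[idx, 7:9, drop = FALSE])
    }
  }

  build <- function(idx) {
    env$K <- env$K + 1L
    j <- env$K
    C <- centroids[idx, , drop = FALSE]
    org <- colMeans(C)
    if (length(idx) >= 2) {
      S <- stats::cov(C)
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)   # decreasing values
      Fr <- e$vectors
      if (det(Fr) < 0) Fr[, 3] <- -Fr[, 3]
    } else {
      Fr <- diag(3)
    }
    Vp <- member_points(idx)
    L <- sweep(Vp, 2, org) %*% Fr
    bmin <- apply(L, 2, min); bmax <- apply(L, 2, max)
    env$frameR[[j]] <- as.vector(Fr)
    env$origin[[j]] <- org
    env$bmin[[j]] <- bmin
    env$bmax[[j]] <- bmax
    ev <- eigvals[idx, , drop = FALSE]
    env$lam_min[[j]] <- apply(ev, 2, min)
    env$lam_max[j] <- max(ev)
    extent <- max(bmax - bmin)
    if (length(idx) <= leaf_capacity ||
        (min_extent > 0 && extent < min_extent)) {
      env$left[j] <- 0L; env$right[j] <- 0L
      env$dstart[j] <- length(env$perm) + 1L
      env$perm <- c(env$perm, idx)
      env$dend[j] <- length(env$perm)
      return(j)
    }
    xloc <- drop(sweep(C, 2, org) %*% Fr[, 1])
    ord <- order(xloc)
    half <- length(idx) %/% 2L
    li <- idx[ord[seq_len(half)]]
    ri <- idx[ord[(half + 1L):length(idx)]]
    env$dstart[j] <- 0L; env$dend[j] <- 0L
    jl <- build(li)
    jr <- build(ri)
    env$left[j] <- jl; env$right[j] <- jr
    j
  }
  build(seq_len(n))

  structure(list(
    kind = kind,
    geom = geom,
    centroids = centroids,
    My = My_m, MSy = MSy_m, Mytot = Mytot_m,
    eigvals = eigvals,
    n_datums = n,
    n_nodes = env$K,
    frameR = do.call(rbind, env$frameR),
    origin = do.call(rbind, env$origin),
    bmin = do.call(rbind, env$bmin),
    bmax = do.call(rbind, env$bmax),
    left = env$left, right = env$right,
    dstart = env$dstart, dend = env$dend,
    perm = env$perm,
    lam_min = do.call(rbind, env$lam_min),
    lam_max = env$lam_max,
    leaf_capacity = leaf_capacity,
    min_extent = min_extent
  ), class = "pdtree")
}

#' @export
print.pdtree <- function(x, ...) {
  cat("PD tree:", x$n_datums, x$kind, "datums,", x$n_nodes, "nodes\n")
  invisible(x)
}

#' Log-determinant lower bound for a PD-tree node
#'
#' Lower bound on `log |R Mx R' + My_i|` over every member datum i of the
#' node: `sum_k log(lambda_x[k] + lambda_node_min[k])`, pairing the
#' ascending eigenvalues of the (rotated) source covariance with the
#' per-rank minima of the member target-covariance eigenvalues. The
#' determinant of a sum of two symmetric PSD matrices is at least the
#' product of their rank-paired eigenvalue sums, with equality when the
#' eigenvector frames align.
#'
#' @param tree a `pdtree`.
#' @param node node index (1 is the root).
#' @param lambda_x ascending eigenvalues of the source covariance (mm^2);
#'   rotation of the source covariance leaves them unchanged.
#' @return Scalar lower bound on the log-determinant term.
#' @export
node_log_min <- function(tree, node, lambda_x) {
  stopifnot(inherits(tree, "pdtree"), node >= 1, node <= tree$n_nodes)
  sum(log(lambda_x + tree$lam_min[node, ]))
}

#' Candidate-bounding ellipsoid for a PD-tree node
#'
#' Region that must contain any target point within the node able to beat
#' the current best match error `E_best`. With the `"sphere"` method the
#' full match covariance is replaced by `(lambda_x_max + lambda_node_max) I`
#' (a bounding sphere); with `"simple_ellipsoid"` only the target part is
#' replaced, giving shape `Mx_rotated + lambda_node_max I` (more compact).
#' The right-hand side is `E_best - node_log_min` for the most-likely
#' criterion; pass `log_min = 0` for criteria without the log term.
#'
#' @inheritParams node_log_min
#' @param x_transformed the transformed source point `R x + t` (mm).
#' @param Mx_rotated rotated source covariance `R Mx R'` (mm^2).
#' @param E_best current best match error.
#' @param method `"simple_ellipsoid"` (default) or `"sphere"`.
#' @param log_min log-determinant lower bound to subtract; defaults to
#'   [node_log_min()] of this node.
#' @return List with `center`, `shape` (3x3 SPD) and `rhs`; the region is
#'   `{z : (z - center)' shape^{-1} (z - center) <= rhs}`, empty when
#'   `rhs <= 0`.
#' @export
node_bound_ellipsoid <- function(tree, node, x_transformed, Mx_rotated,
                                 E_best,
                                 method = c("simple_ellipsoid", "sphere"),
                                 log_min = NULL) {
  method <- match.arg(method)
  Mx_rotated <- check_cov3(Mx_rotated, "Mx_rotated")
  if (is.null(log_min)) {
    lambda_x <- eig3_spd(Mx_rotated)$values
    log_min <- node_log_min(tree, node, lambda_x)
  }
  lam_max <- tree$lam_max[node]
  shape <- if (method == "sphere") {
    (eig3_spd(Mx_rotated)$values[3] + lam_max) * diag(3)
  } else {
    Mx_rotated + lam_max * diag(3)
  }
  list(center = as.numeric(x_transformed), shape = shape,
       rhs = E_best - log_min)
}

#' Ellipsoid vs oriented-bounding-box intersection test
#'
#' Sound, conservative test used for node pruning: it never reports "no
#' intersection" when the ellipsoid and the node's box share a point, but
#' may report an intersection for a near miss (which only costs search
#' time). For spherical shapes the exact closest-point-on-box distance is
#' used; for general ellipsoids the ellipsoid's support extents along the
#' node's local axes are compared against the box.
#'
#' @param e an ellipsoid as returned by [node_bound_ellipsoid()].
#' @param tree a `pdtree`.
#' @param node node index.
#' @return Logical.
#' @export
ellipsoid_intersects_obb <- function(e, tree, node) {
  if (e$rhs <= 0) return(FALSE)
  Fr <- matrix(tree$frameR[node, ], 3, 3)
  cl <- drop(crossprod(Fr, e$center - tree$origin[node, ]))
  bmin <- tree$bmin[node, ]; bmax <- tree$bmax[node, ]
  shape <- e$shape
  iso <- max(abs(shape - shape[1, 1] * diag(3))) < 1e-12 * max(1, abs(shape[1, 1]))
  if (iso) {
    r2 <- e$rhs * shape[1, 1]
    ex <- pmax(0, pmax(bmin - cl, cl - bmax))
    return(sum(ex^2) <= r2)
  }
  for (k in 1:3) {
    a <- Fr[, k]
    h <- sqrt(e$rhs * drop(a %*% shape %*% a))
    if (cl[k] - h > bmax[k] || cl[k] + h < bmin[k]) return(FALSE)
  }
  TRUE
}
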