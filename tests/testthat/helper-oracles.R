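# Shared fixtures and independent oracles for the test suite.

cross3_r <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# truncated-series matrix exponential (oracle for the Rodrigues formula)
expm_series <- function(K, terms = 40) {
  S <- diag(3); P <- diag(3)
  for (n in seq_len(terms)) {
    P <- P %*% K / n
    S <- S + P
  }
  S
}

# random symmetric positive definite matrix with eigenvalues in a range
rand_spd <- function(lo = 0.2, hi = 3) {
  random_covariance(sort(runif(3, lo, hi)))
}

# dense assembly of the Gauss-Newton normal equations (oracle for gn_step):
# builds the full 3n x 6 Jacobian and 3n x 3n block covariance explicitly
gn_step_dense <- function(X, Y, Mx, My, T_, rotation_only = FALSE) {
  n <- nrow(X)
  R <- T_$R
  p <- if (rotation_only) 3 else 6
  J <- matrix(0, 3 * n, p)
  Minv <- matrix(0, 3 * n, 3 * n)
  F0 <- numeric(3 * n)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    u <- drop(R %*% X[i, ])
    S <- skew(u)
    J[rows, 1:3] <- S
    if (!rotation_only) J[rows, 4:6] <- -diag(3)
    M <- R %*% Mx[, , i] %*% t(R) + My[, , i]
    Minv[rows, rows] <- solve(M)
    F0[rows] <- Y[i, ] - u - T_$t
  }
  A <- t(J) %*% Minv %*% J
  drop(solve(A, -t(J) %*% Minv %*% F0))
}

# full-R exhaustive most-likely match over point datums (oracle for the
# PD-tree search, independent of all C++ code)
exhaustive_match_r <- function(points, My_list, x, Mx, T_,
                               criterion = "mlp") {
  best <- Inf; best_i <- NA_integer_
  xt <- apply_transform(T_, x)
  for (i in seq_len(nrow(points))) {
    y <- points[i, ]
    e <- switch(criterion,
                mlp = match_error(x, y, Mx, My_list[[i]], T_),
                md = sqr_mahalanobis(x, y, Mx, My_list[[i]], T_),
                closest_point = sum((y - xt)^2))
    if (e < best) { best <- e; best_i <- i }
  }
  list(idx = best_i, err = best)
}

# barycentric-grid minimizer of the quadratic form over a triangle
# (oracle for the per-datum most-likely point)
tri_grid_quad <- function(V, x, W, steps = 500) {
  s <- rep(seq(0, 1, length.out = steps + 1), each = steps + 1)
  t <- rep(seq(0, 1, length.out = steps + 1), times = steps + 1)
  keep <- s + t <= 1
  s <- s[keep]; t <- t[keep]
  Z <- cbind(1 - s - t, s, t) %*% V
  D <- sweep(Z, 2, x)
  q <- rowSums((D %*% W) * D)
  k <- which.min(q)
  list(y = Z[k, ], quad = q[k])
}

# collect the datum members of every node by walking the stored tree
node_members <- function(tree) {
  members <- vector("list", tree$n_nodes)
  walk <- function(j) {
    if (tree$left[j] == 0) {
      members[[j]] <<- sort(tree$perm[tree$dstart[j]:tree$dend[j]])
    } else {
      walk(tree$left[j])
      walk(tree$right[j])
      members[[j]] <<- sort(c(members[[tree$left[j]]],
                              members[[tree$right[j]]]))
    }
  }
  walk(1)
  members
}

# small synthetic registration trial on a fixture mesh: noisy surface
# samples (plus optional outliers) under a random misalignment
mesh_trial <- function(mesh, n_points = 100, case_id = 6, outlier_frac = 0,
                       trans_range = c(15, 30), rot_range = c(15, 30)) {
  s <- sample_mesh_points(mesh, n_points)
  noisy <- apply_noise_case(s$points, s$normals, noise_case(case_id))
  X0 <- noisy$points
  Mx0 <- noisy$Mx
  n_out <- round(outlier_frac * n_points)
  if (n_out > 0) {
    X0 <- rbind(X0, gen_outlier_points(mesh, n_out))
    iso <- array(noise_case(case_id)$sigma_normal^2 * diag(3),
                 c(3, 3, n_out))
    Mx0 <- array(c(Mx0, iso), c(3, 3, n_points + n_out))
  }
  T_mis <- random_misalignment(trans_range, rot_range)
  T_inv <- invert_transform(T_mis)
  X <- apply_transform(T_inv, X0)
  Mx <- Mx0
  for (i in seq_len(dim(Mx)[3]))
    Mx[, , i] <- T_inv$R %*% Mx[, , i] %*% t(T_inv$R)
  list(X = X, Mx = Mx, T_true = T_mis,
       validation = sample_mesh_points(mesh, 100)$points)
}
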