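test_that("tree construction satisfies the containment and summary
          invariants on a random point cloud", {
  set.seed(301)
  n <- 200
  P <- matrix(runif(3 * n, -100, 100), n, 3)
  My <- lapply(1:n, function(i) rand_spd())
  tree <- build_pdtree(P, My = My)
  members <- node_members(tree)
  expect_equal(members[[1]], 1:n)       # root holds everything
  leaf <- which(tree$left == 0)
  expect_equal(sort(unlist(lapply(leaf, function(j)
    tree$perm[tree$dstart[j]:tree$dend[j]]))), 1:n)
  eigs <- t(vapply(My, function(M) eig3_spd(M)$values, numeric(3)))
  for (j in seq_len(tree$n_nodes)) {
    idx <- members[[j]]
    Fr <- matrix(tree$frameR[j, ], 3, 3)
    L <- sweep(P[idx, , drop = FALSE], 2, tree$origin[j, ]) %*% Fr
    expect_true(all(sweep(L, 2, tree$bmin[j, ]) >= -1e-9))
    expect_true(all(sweep(L, 2, tree$bmax[j, ]) <= 1e-9))
    # per-rank lambda summaries equal brute-force extrema over members
    expect_equal(tree$lam_min[j, ],
                 apply(eigs[idx, , drop = FALSE], 2, min),
                 tolerance = 1e-12)
    expect_equal(tree$lam_max[j], max(eigs[idx, ]), tolerance = 1e-12)
    if (tree$left[j] > 0) {
      l <- tree$left[j]; r <- tree$right[j]
      expect_equal(sort(c(members[[l]], members[[r]])), idx)
      expect_true(all(tree$lam_min[l, ] >= tree$lam_min[j, ] - 1e-12))
      expect_true(all(tree$lam_min[r, ] >= tree$lam_min[j, ] - 1e-12))
      expect_lte(tree$lam_max[l], tree$lam_max[j] + 1e-12)
    }
  }
  expect_true(all(vapply(leaf, function(j)
    tree$dend[j] - tree$dstart[j] + 1 <= tree$leaf_capacity, logical(1))))
})

test_that("root frame aligns with the dominant direction; single datum
          degenerates to a point box", {
  d <- c(1, 1, 1) / sqrt(3)
  P <- outer(seq(-50, 50, length.out = 40), d)
  tree <- build_pdtree(P)
  expect_equal(abs(sum(tree$frameR[1, 1:3] * d)), 1, tolerance = 1e-9)
  t1 <- build_pdtree(matrix(c(1, 2, 3), 1, 3))
  expect_equal(t1$n_nodes, 1L)
  expect_equal(t1$bmin[1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(t1$bmax[1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_error(build_pdtree(matrix(numeric(0), 0, 3)), "empty")
})

test_that("triangle trees bound every member vertex", {
  set.seed(302)
  mesh <- make_synthetic_mesh("ellipsoid", subdivisions = 2)
  tree <- build_pdtree(mesh)
  members <- node_members(tree)
  for (j in sample(seq_len(tree$n_nodes), 20)) {
    idx <- members[[j]]
    Vp <- rbind(tree$geom[idx, 1:3, drop = FALSE],
                tree$geom[idx, 4:6, drop = FALSE],
                tree$geom[idx, 7:9, drop = FALSE])
    Fr <- matrix(tree$frameR[j, ], 3, 3)
    L <- sweep(Vp, 2, tree$origin[j, ]) %*% Fr
    expect_true(all(sweep(L, 2, tree$bmin[j, ]) >= -1e-9))
    expect_true(all(sweep(L, 2, tree$bmax[j, ]) <= 1e-9))
  }
})

test_that("node_log_min lower-bounds the member log-determinants", {
  # single member, identity covariance, aligned-isotropic equality case
  t1 <- build_pdtree(matrix(0, 1, 3), My = diag(3))
  expect_equal(node_log_min(t1, 1, c(1, 1, 1)), log(8), tolerance = 1e-12)
  expect_equal(node_log_min(t1, 1, c(0, 0, 0)), 0, tolerance = 1e-12)
  set.seed(303)
  n <- 50
  My <- lapply(1:n, function(i) rand_spd())
  tree <- build_pdtree(matrix(runif(3 * n, -10, 10), n, 3), My = My)
  for (k in 1:100) {
    Mx <- rand_spd()
    R <- random_rotation()
    lam_x <- eig3_spd(Mx)$values
    bound <- node_log_min(tree, 1, lam_x)
    true_min <- min(vapply(My, function(M)
      log(det(R %*% Mx %*% t(R) + M)), numeric(1)))
    expect_lte(bound, true_min + 1e-10)
  }
})

test_that("bound ellipsoids are sound: better-match points lie inside", {
  set.seed(304)
  n <- 20
  P <- matrix(runif(3 * n, -5, 5), n, 3)
  My <- lapply(1:n, function(i) rand_spd(0.2, 1.5))
  tree <- build_pdtree(P, My = My)
  T_ <- rigid_transform(random_rotation(), rnorm(3))
  x <- runif(3, -5, 5)
  Mx <- rand_spd(0.2, 1.5)
  Mxr <- T_$R %*% Mx %*% t(T_$R)
  xt <- apply_transform(T_, x)
  E_best <- match_error(x, P[1, ], Mx, My[[1]], T_) + 1
  members <- node_members(tree)
  for (method in c("simple_ellipsoid", "sphere")) {
    for (j in c(1, 2, tree$n_nodes)) {
      e <- node_bound_ellipsoid(tree, j, xt, Mxr, E_best, method = method)
      Winv <- solve(e$shape)
      for (s in 1:300) {
        i <- sample(members[[j]], 1)
        z <- xt + rnorm(3, sd = 3)
        err <- match_error(x, z, Mx, My[[i]], T_)
        if (err < E_best) {
          d <- z - e$center
          expect_lte(drop(d %*% Winv %*% d), e$rhs + 1e-9)
        }
      }
    }
  }
  # spherical shape arithmetic: Mx = I, lam_node_max scales the radius
  tI <- build_pdtree(matrix(0, 1, 3), My = diag(3))
  eb <- node_bound_ellipsoid(tI, 1, c(0, 0, 0), diag(3), E_best = 5,
                             method = "sphere", log_min = 0)
  expect_equal(eb$shape, 2 * diag(3))
  expect_equal(eb$rhs, 5)
})

test_that("ellipsoid-OBB test has no false negatives", {
  set.seed(305)
  # unit sphere centered inside the box of a small cloud
  P <- matrix(runif(30, -1, 1), 10, 3)
  tree <- build_pdtree(P)
  e_in <- list(center = tree$origin[1, ], shape = diag(3), rhs = 1)
  expect_true(ellipsoid_intersects_obb(e_in, tree, 1))
  # far-away sphere misses a tiny box
  Pt <- matrix(runif(30, -0.5, 0.5), 10, 3)
  tt <- build_pdtree(Pt)
  e_far <- list(center = tt$origin[1, ] + c(10, 0, 0), shape = diag(3),
                rhs = 1)
  expect_false(ellipsoid_intersects_obb(e_far, tt, 1))
  expect_false(ellipsoid_intersects_obb(
    list(center = c(0, 0, 0), shape = diag(3), rhs = -1), tt, 1))
  # randomized soundness: whenever a sampled common point exists the test
  # must report intersection
  hits <- 0
  for (k in 1:200) {
    Pk <- matrix(runif(24, -2, 2), 8, 3)
    trk <- build_pdtree(Pk)
    shape <- rand_spd(0.1, 2)
    center <- runif(3, -4, 4)
    rhs <- runif(1, 0.1, 4)
    L <- t(chol(shape * rhs))
    hit <- FALSE
    for (s in 1:50) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
      z <- center + drop(L %*% u)
      Fr <- matrix(trk$frameR[1, ], 3, 3)
      zl <- drop(crossprod(Fr, z - trk$origin[1, ]))
      if (all(zl >= trk$bmin[1, ] - 1e-12) &&
          all(zl <= trk$bmax[1, ] + 1e-12)) { hit <- TRUE; break }
    }
    if (hit) {
      hits <- hits + 1
      expect_true(ellipsoid_intersects_obb(
        list(center = center, shape = shape, rhs = rhs), trk, 1))
    }
  }
  expect_gt(hits, 20)  # the random setup produced genuine intersections
})
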