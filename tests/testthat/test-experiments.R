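test_that("trial generator honors the stated protocol", {
  set.seed(701)
  tr <- gen_experiment1_trial()
  expect_equal(dim(tr$ground_truth), c(50L, 3L))
  expect_true(all(abs(tr$ground_truth) <= 100))
  for (i in c(1, 25, 50)) {
    expect_equal(det(tr$Mx[, , i]), 0.5, tolerance = 1e-9)
    expect_equal(det(tr$My[, , i]), 0.5, tolerance = 1e-9)
  }
  # per-set orientation: all covariances within one set are identical
  expect_equal(tr$Mx[, , 1], tr$Mx[, , 50], tolerance = 1e-12)
  tr2 <- gen_experiment1_trial(orientation = "per_point")
  expect_gt(max(abs(tr2$Mx[, , 1] - tr2$Mx[, , 50])), 1e-6)
  # zero noise: noisy sets equal the (misaligned) ground truth
  tr0 <- gen_experiment1_trial(eigs_source = c(0, 0, 0),
                               eigs_target = c(0, 0, 0))
  expect_equal(tr0$X, tr0$X_clean, tolerance = 1e-12)
  expect_equal(tr0$Y, tr0$ground_truth, tolerance = 1e-12)
  # the misalignment transform maps the clean source onto the truth
  expect_equal(apply_transform(tr$T_true, tr$X_clean), tr$ground_truth,
               tolerance = 1e-9)
})

test_that("generated noise matches its covariance by moments", {
  set.seed(702)
  tr <- gen_experiment1_trial(n = 4000, trans_range = c(0, 0),
                              rot_range = c(0, 0))
  resid <- tr$Y - tr$ground_truth
  S <- crossprod(resid) / nrow(resid)
  ev <- sort(eigen(S, symmetric = TRUE)$values)
  # pooled covariance must reproduce the generating eigenvalues; the
  # eigenvalue sampling error at n = 4000 is ~ lambda * sqrt(2/n)
  expect_equal(ev, c(0.5, 0.5, 2), tolerance = 0.15)
  expect_equal(S, tr$My[, , 1], tolerance = 0.2)
})

test_that("registration-error metrics behave as distances", {
  P <- matrix(runif(30, -10, 10), 10, 3)
  expect_equal(registration_error(rigid_transform(), P, P), 0)
  expect_equal(registration_error(rigid_transform(t = c(1, 0, 0)), P, P), 1)
  # small rotation about z on an xy-circle of radius r moves points ~ r*delta
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  C <- cbind(10 * cos(th), 10 * sin(th), 0)
  delta <- 1e-3
  re <- registration_error(rigid_transform(rodrigues(c(0, 0, delta))), C, C)
  expect_equal(re, 10 * delta, tolerance = 1e-4)
  V <- matrix(runif(30), 10, 3)
  expect_equal(target_registration_error(rigid_transform(), rigid_transform(), V), 0)
  Tb <- rigid_transform(t = c(0, 0, 2))
  expect_equal(target_registration_error(Tb, rigid_transform(), V), 2)
  expect_equal(target_registration_error(Tb, rigid_transform(), V),
               target_registration_error(rigid_transform(), Tb, V))
})

test_that("surface sampling is area-weighted", {
  m1 <- imlp_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  matrix(c(1, 2, 3), 1))
  set.seed(703)
  s <- sample_mesh_points(m1, 50)
  expect_equal(nrow(s$points), 50)
  expect_true(all(abs(s$points[, 3]) < 1e-12))
  expect_true(all(s$points[, 1] + s$points[, 2] <= 1 + 1e-9))
  # two triangles with areas 1 and 9
  m2 <- imlp_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0),
                        c(0, 0, 5), c(6, 0, 5), c(0, 3, 5)),
                  rbind(c(1, 2, 3), c(4, 5, 6)))
  s2 <- sample_mesh_points(m2, 10000)
  frac_big <- mean(attr(s2, "face") == 2)
  expect_lt(abs(frac_big - 0.9), 3 * sqrt(0.09 / 10000) + 0.001)
})

test_that("noise cases reproduce the tabulated variances", {
  set.seed(704)
  nrm <- matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE)
  P <- matrix(runif(15), 5, 3)
  c1 <- apply_noise_case(P, nrm, noise_case(1))
  expect_equal(c1$Mx[, , 1], 0.25 * diag(3), tolerance = 1e-12)
  c6 <- apply_noise_case(P, nrm, noise_case(6))
  expect_equal(drop(nrm[1, ] %*% c6$Mx[, , 1] %*% nrm[1, ]), 4,
               tolerance = 1e-12)
  expect_equal(sort(eigen(c6$Mx[, , 1], symmetric = TRUE)$values),
               c(0.25, 0.25, 4), tolerance = 1e-12)
  z <- apply_noise_case(P, nrm, noise_case(sigma_normal = 0,
                                           sigma_parallel = 0))
  expect_equal(z$points, P)
  # random-global shares one orientation, random-per-point does not
  g <- apply_noise_case(P, NULL, noise_case(sigma_normal = 2,
                                            sigma_parallel = 0.5,
                                            orientation = "random_global"))
  expect_equal(g$Mx[, , 1], g$Mx[, , 5], tolerance = 1e-12)
  pp <- apply_noise_case(P, NULL, noise_case(sigma_normal = 2,
                                             sigma_parallel = 0.5,
                                             orientation = "random_per_point"))
  expect_gt(max(abs(pp$Mx[, , 1] - pp$Mx[, , 5])), 1e-6)
})

test_that("outliers project outward from the surface by the stated range", {
  set.seed(705)
  mesh <- make_synthetic_mesh("icosphere", subdivisions = 3, radius = 50)
  out <- gen_outlier_points(mesh, 200, c(10, 20))
  expect_equal(nrow(out), 200)
  radii <- sqrt(rowSums(out^2))
  expect_true(all(radii > 50 + 10 - 1.5))   # facet-chord tolerance
  expect_true(all(radii < 50 + 20 + 0.5))
})

test_that("synthetic fixture meshes are watertight and correctly sized", {
  ico <- make_synthetic_mesh("icosphere", subdivisions = 3)
  expect_equal(nrow(ico$faces), 1280)   # 20 * 4^3
  ell <- make_synthetic_mesh("ellipsoid", subdivisions = 2,
                             axes = c(50, 70, 90))
  expect_equal(apply(abs(ell$vertices), 2, max), c(50, 70, 90),
               tolerance = 1e-9)
  bumpy <- make_synthetic_mesh("bumpy_sphere", subdivisions = 2)
  for (m in list(ico, ell, bumpy)) {
    edges <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    expect_true(all(table(key) == 2))   # every edge shared by two faces
    V <- nrow(m$vertices); E <- length(unique(key)); F <- nrow(m$faces)
    expect_equal(V - E + F, 2)          # Euler characteristic of a sphere
  }
})

test_that("benchmark rows are deterministic under a fixed seed", {
  r1 <- run_experiment1_bin("A", c(10, 20), c(0, 15), trials = 2, seed = 9)
  r2 <- run_experiment1_bin("A", c(10, 20), c(0, 15), trials = 2, seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)
  expect_true(all(r1$mean_re > 0))
})
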