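test_that("skew encodes the cross product and is antisymmetric", {
  expect_equal(drop(skew(c(1, 0, 0)) %*% c(0, 1, 0)), c(0, 0, 1))
  set.seed(101)
  for (k in 1:20) {
    v <- rnorm(3); w <- rnorm(3)
    expect_equal(drop(skew(v) %*% w), cross3_r(v, w), tolerance = 1e-12)
    expect_equal(drop(skew(v) %*% v), rep(0, 3), tolerance = 1e-12)
    expect_equal(t(skew(v)), -skew(v))
  }
})

test_that("rodrigues matches the matrix exponential of the skew matrix", {
  expect_equal(rodrigues(c(0, 0, 0)), diag(3))
  expect_equal(rodrigues(c(pi, 0, 0)), diag(c(1, -1, -1)), tolerance = 1e-12)
  set.seed(102)
  for (k in 1:25) {
    alpha <- rnorm(3) * runif(1, 0.001, 2)
    R <- rodrigues(alpha)
    expect_equal(R, expm_series(skew(alpha)), tolerance = 1e-12)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("rotation_log inverts rodrigues, stably near 0 and pi", {
  expect_equal(rotation_log(diag(3)), c(0, 0, 0))
  v <- rotation_log(diag(c(1, -1, -1)))
  expect_equal(norm_v <- sqrt(sum(v^2)), pi, tolerance = 1e-9)
  expect_equal(abs(v[1]) / norm_v, 1, tolerance = 1e-9)
  set.seed(103)
  for (ang in c(1e-9, 1e-6, 1e-3, 0.1, 1, 2, 3, pi - 1e-6, pi - 1e-10)) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    R <- rodrigues(axis * ang)
    a <- rotation_log(R)
    expect_equal(rodrigues(a), R, tolerance = 1e-9)
    expect_lte(sqrt(sum(a^2)), pi + 1e-12)
  }
  for (k in 1:20) {
    R <- random_rotation()
    expect_equal(rodrigues(rotation_log(R)), R, tolerance = 1e-9)
  }
  expect_error(rotation_log(diag(3) * 2), "rotation")
})

test_that("random_covariance preserves the eigenvalue multiset", {
  set.seed(104)
  M <- random_covariance(c(0.5, 0.5, 2))
  expect_equal(det(M), 0.5, tolerance = 1e-9)
  expect_equal(eig3_spd(M)$values, c(0.5, 0.5, 2), tolerance = 1e-9)
  expect_equal(random_covariance(c(1, 1, 1)), diag(3), tolerance = 1e-12)
  expect_error(random_covariance(c(-1, 1, 1)), "negative")
  for (k in 1:20) {
    eigs <- sort(runif(3, 0, 5))
    expect_equal(eig3_spd(random_covariance(eigs))$values, eigs,
                 tolerance = 1e-9)
  }
})

test_that("random covariance orientations have no preferred axis", {
  set.seed(105)
  ndraw <- 2000
  U <- t(replicate(ndraw, eig3_spd(random_covariance(c(0.3, 1, 4)))$vectors[, 3]))
  # squared components of a uniform direction have mean 1/3, var 4/45
  se3 <- 3 * sqrt(4 / 45 / ndraw)
  for (j in 1:3)
    expect_lt(abs(mean(U[, j]^2) - 1 / 3), se3)
})

test_that("surface_covariance splits variance normal vs tangential", {
  expect_equal(surface_covariance(c(0, 0, 1), 1, 0.5),
               diag(c(0.25, 0.25, 1)), tolerance = 1e-12)
  expect_equal(surface_covariance(c(1, 0, 0), 0.7, 0.7), 0.49 * diag(3),
               tolerance = 1e-12)
  set.seed(106)
  for (k in 1:20) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    M <- surface_covariance(nrm, 2, 0.5)
    expect_equal(drop(nrm %*% M %*% nrm), 4, tolerance = 1e-12)
    expect_equal(sort(eigen(M, symmetric = TRUE)$values),
                 c(0.25, 0.25, 4), tolerance = 1e-12)
  }
  expect_error(surface_covariance(c(0, 0, 0), 1, 1), "zero normal")
})

test_that("eig3_spd gives ascending eigenvalues matching the
          characteristic polynomial", {
  expect_equal(eig3_spd(diag(c(3, 1, 2)))$values, c(1, 2, 3))
  expect_equal(eig3_spd(diag(3))$values, c(1, 1, 1))
  set.seed(107)
  for (k in 1:20) {
    M <- rand_spd()
    e <- eig3_spd(M)
    expect_equal(diff(e$values) >= -1e-12, c(TRUE, TRUE))
    # roots of det(M - lambda I) via the cubic characteristic polynomial
    m2 <- sum(vapply(1:3, function(i) det(M[-i, -i, drop = FALSE]),
                     numeric(1)))
    roots <- polyroot(c(-det(M), m2, -sum(diag(M)), 1))
    expect_equal(sort(Re(roots)), e$values, tolerance = 1e-8)
    expect_equal(e$vectors %*% diag(e$values) %*% t(e$vectors), M,
                 tolerance = 1e-9)
    expect_equal(crossprod(e$vectors), diag(3), tolerance = 1e-9)
  }
  expect_error(eig3_spd(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)),
               "symmetric")
})

test_that("rigid transforms validate, compose and invert", {
  T1 <- rigid_transform(rodrigues(c(0, 0, pi / 2)), c(1, 2, 3))
  expect_equal(apply_transform(T1, c(1, 0, 0)), c(1, 3, 3), tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 1.01, c(0, 0, 0)), "rotation")
  set.seed(108)
  Ta <- rigid_transform(random_rotation(), rnorm(3))
  Tb <- rigid_transform(random_rotation(), rnorm(3))
  x <- rnorm(3)
  expect_equal(apply_transform(compose_transform(Ta, Tb), x),
               apply_transform(Ta, apply_transform(Tb, x)),
               tolerance = 1e-12)
  expect_equal(apply_transform(invert_transform(Ta),
                               apply_transform(Ta, x)), x,
               tolerance = 1e-12)
})
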