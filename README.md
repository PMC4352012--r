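# imlp: Iterative Most-Likely Point registration of 3D shapes

Rigid-body registration of a measured 3D point set to a target shape (a
triangle mesh or a point cloud) when the measurement noise is
**anisotropic** and may differ from point to point — the typical situation
for optically or magnetically tracked probes, stereo reconstructions and
segmented anatomical surfaces in image-guided interventions. Standard ICP
treats every match as an isotropic, equally weighted distance; `imlp`
implements the Iterative Most-Likely Point (IMLP) algorithm, which carries
a full 3×3 Gaussian covariance for every source and target point through
both phases of the ICP-style iteration.

## The model

A match between a transformed source point and a target point is scored by
the negative log of its Gaussian likelihood, the *match error*

```
E(x, y) = log | R Mx Rᵀ + My |
        + (y − R x − t)ᵀ (R Mx Rᵀ + My)⁻¹ (y − R x − t)
```

with `Mx`, `My` the per-point noise covariances (mm²). Each outer
iteration:

1. **Correspondence phase** — for every source point, finds the point on
   the target shape minimizing `E` over *all* datums (mesh triangles or
   cloud points). The search uses a principal-direction (PD) tree whose
   nodes carry oriented bounding boxes and eigenvalue summaries of the
   member covariances; a node is pruned only when a sound ellipsoid bound
   proves it cannot beat the current best error, so the result is exactly
   the global optimum of each query.
2. **Noise-model update** — a *match-uncertainty* variance `σ² = mean
   squared inlier residual` (capped by `sigma2_max`) absorbs the residual
   misalignment; matches whose squared Mahalanobis distance (measurement
   covariances only, 3 d.o.f. chi-square) exceeds `chi2_thresh` (default
   7.81, the 0.95 quantile) are flagged as outliers and their noise models
   inflated by `φ = 9 d²` (or the matches discarded).
3. **Registration phase** — the transform is re-estimated by generalized
   total least squares: Gauss-Newton on the sum of squared Mahalanobis
   residuals, with the Jacobian blocks `[skew(R xᵢ) | −I]`, block-diagonal
   combined covariances refreshed every iteration, and Rodrigues updates
   that keep `R` exactly orthonormal.

Setting the match criterion to plain Mahalanobis distance or Euclidean
distance gives the IMLP-MD and IMLP-CP variants; `icp_register()` provides
standard ICP for comparison.

## Worked example

Register 100 noisy surface samples (surface-conditioned anisotropic noise,
σ = 2 mm along the normal, 0.5 mm tangentially) plus 10 gross outliers
back to a synthetic bumpy-sphere mesh after a random misalignment of
15–30 mm / 15–30°:

```r
library(imlp)
set.seed(42)
mesh <- make_synthetic_mesh("bumpy_sphere", subdivisions = 3)
tree <- build_pdtree(mesh)

samp  <- sample_mesh_points(mesh, 100)
noisy <- apply_noise_case(samp$points, samp$normals, noise_case(6))
X0  <- rbind(noisy$points, gen_outlier_points(mesh, 10, c(10, 20)))
Mx0 <- array(c(noisy$Mx, array(4 * diag(3), c(3, 3, 10))), c(3, 3, 110))

T_mis <- random_misalignment(c(15, 30), c(15, 30))
T_inv <- invert_transform(T_mis)
X  <- apply_transform(T_inv, X0)
Mx <- Mx0
for (i in 1:110) Mx[, , i] <- T_inv$R %*% Mx[, , i] %*% t(T_inv$R)

fit <- imlp_register(source_shape(X, Mx), tree)
sum(fit$outlier_mask)
#> [1] 10
validation <- sample_mesh_points(mesh, 100)$points
target_registration_error(fit$transform, T_mis, validation)
#> [1] 1.245075
icp <- icp_register(X, tree)
target_registration_error(icp$transform, T_mis, validation)
#> [1] 7.379929
```

All 10 planted outliers are flagged by the chi-square test, and the target
registration error (mean displacement of 100 independent validation
points under the estimated vs. the true transform) is 1.2 mm for IMLP
against 7.4 mm for standard ICP, whose least-squares fit is dragged by the
outliers.

The GTLS solver is also usable on its own for pre-matched point sets:

```r
tr  <- gen_experiment1_trial()          # 50 corresponding noisy pairs
fit <- register_corresponding_gtls(tr$X, tr$Y, tr$Mx, tr$My)
registration_error(fit$transform, tr$X_clean, tr$ground_truth)
```

A command-line front end (`inst/cli/imlp.R`) exposes `register`,
`gtls-align` and `experiment1` subcommands over PLY/STL/OFF meshes, CSV
covariance side-files and JSON transforms.

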