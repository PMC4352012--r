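---
title: "Anisotropic-noise rigid registration with imlp: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic-noise rigid registration with imlp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imlp)
```

## The problem

Surface-based rigid registration aligns a set of measured 3D points with a
model of the same shape — a segmented bone surface, a statue scan, a
tracked probe's sample cloud. The measurements are rarely isotropic:
optical trackers are more precise laterally than along the viewing axis,
stereo reconstructions degrade with depth, and a point sampled from a
surface constrains the alignment tightly along the surface normal but
barely at all tangentially. Classic ICP ignores all of this, matching by
Euclidean distance and fitting by unweighted least squares.

`imlp` implements the Iterative Most-Likely Point algorithm, which treats
every source point \(\vec x_i\) and every target point \(\vec y_i\) as a
Gaussian measurement with its own 3×3 covariance and alternates:

* **correspondence** — each source point is matched to the target point
  maximizing the Gaussian match likelihood under the current transform
  \([R, \vec t\,]\), equivalently minimizing the *match error*
  \[
  E = \log\lvert R M_{x} R^\top + M_{y}\rvert +
      (\vec y - R\vec x - \vec t\,)^\top (R M_x R^\top + M_y)^{-1}
      (\vec y - R\vec x - \vec t\,),
  \]
* **registration** — with matches fixed, \([R, \vec t\,]\) is re-estimated
  by minimizing the summed squared Mahalanobis residuals (the
  log-determinant term changes only weakly with \(R\) and is dropped in
  this phase), a generalized total-least-squares (GTLS) problem.

The log term in the correspondence phase matters whenever target noise
models vary in magnitude *or orientation* across the shape; dropping it
gives the Mahalanobis-distance variant (`criterion = "md"`), and dropping
the covariances entirely gives closest-point matching
(`criterion = "closest_point"`). Both variants are provided because they
isolate the contribution of the matching criterion.

## Noise model components

Each source point carries a measurement covariance `Mx` and optionally a
*surface-model* covariance `MSx` (large tangential eigenvalues,
`surface_covariance()`), which models the unmeasured surface patch around
a sample when the target is itself a sparse point cloud. Target datums
carry `My`/`MSy` likewise. Two dynamic terms complete the model:

* **match uncertainty** \(\sigma^2\): the mean squared residual over the
  current inliers, added isotropically (to the source side during
  matching, the target side during registration — algebraically
  equivalent, the placement minimizes recomputation). Early on
  \(\sigma^2\) is dominated by misalignment, which keeps the chi-square
  test from flagging everything; it shrinks as the shapes align. The cap
  `sigma2_max` exists for partial-overlap problems where the mean squared
  residual never becomes small; together with `outlier_mode = "discard"`
  this is the package's partial-overlap mechanism.
* **outlier inflation** \(\varphi_i = 9 d_i^2\) for matches whose squared
  Mahalanobis distance (measurement covariances only — the surface model
  is deliberately excluded, which sharpens rejection) exceeds
  `chi2_thresh`. The default 7.81 is the 0.95 quantile of
  \(\chi^2_3\) (`qchisq(0.95, 3)`); 6.25 corresponds to 0.90. The factor
  9 leaves a flagged residual at about one third of a standard deviation
  of its inflated model, effectively removing its pull. The inflation is
  split as \(\varphi_i/2\) on each side of the match so the *combined*
  covariance grows by exactly \(\varphi_i\); this is the reading of the
  update that is consistent with the one-third-standard-deviation
  rationale, and the one implemented.

With `chi2_thresh = Inf` and `sigma2_max = Inf` the whole mechanism is
inert and IMLP reduces to covariance-weighted ICP.

## Correspondence search: PD tree with sound pruning

The target is indexed once in a principal-direction tree
(`build_pdtree()`): each node's frame is the eigenbasis of its datum
centroids' covariance (x-axis = greatest variance), its box is the
minimal frame-aligned box containing *every vertex* of its member datums,
and splitting is at the median local-x centroid coordinate, giving a
balanced tree (the median-vs-midpoint choice is ours; leaf capacity
defaults to 5 datums, and the box-extent stopping rule is available but
disabled by default). Nodes store two noise summaries over their members:
the per-rank minima of the target-covariance eigenvalues and the maximum
eigenvalue.

A query prunes a node when no point in its box can beat the current best
error \(E_{best}\). Any such point would lie in the ellipsoid
\[
(\vec z - R\vec x - \vec t\,)^\top M_{sub}^{-1}
(\vec z - R\vec x - \vec t\,) \le E_{best} - \log_{min},
\]
where \(\log_{min} = \sum_k \log(\lambda_{x,k} + \lambda_{node\_min,k})\)
lower-bounds the log-determinant over the node (the determinant of a sum
of symmetric PSD matrices is at least the product of rank-paired
eigenvalue sums, with equality for aligned eigenframes — hence the fixed
ascending eigenvalue ordering used throughout the package), and
\(M_{sub}\) replaces the match covariance by something at least as large
in every direction: either \((\lambda_{x\_max} + \lambda_{node\_max}) I\)
(`bound = "sphere"`) or \(R M_x R^\top + \lambda_{node\_max} I\)
(`bound = "simple_ellipsoid"`, the default — more compact, still cheap).
A third, minimal-volume bound over the member covariance ellipsoids
exists in the literature but is not implemented here.

The ellipsoid–box overlap test is deliberately conservative: for
spherical shapes the exact closest-point-on-box distance is used; for
general ellipsoids the ellipsoid's support extents along the node's three
axes are compared against the box. Conservativeness can only cost visits,
never correctness, and the exactness of the whole search is enforced in
the test suite by comparison with exhaustive evaluation across criteria,
datum kinds and bound methods. On triangle datums the per-datum
most-likely point is the minimizer of the quadratic form over the closed
triangle, solved exactly: the 2×2 interior stationary point if feasible,
otherwise the best clamped point over the three edges. Ties between
datums break to the lowest datum index, and warm-starting a query with
the previous iteration's match seeds \(E_{best}\) without ever changing
the returned optimum.

## Registration phase: Gauss-Newton GTLS

Linearizing the constraint \(\vec y_i^* = R \vec x_i^* + \vec t\) with the
skew-matrix form of an incremental rotation gives, per pair, the Jacobian
block \([\,\mathrm{skew}(R_k \vec x_i) \mid -I\,]\) and the normal
equations
\[
J^\top M^{-1} J\, \Delta p = -J^\top M^{-1} F^0,
\]
with \(M\) block-diagonal (blocks \(R_k M_{x_i} R_k^\top + M_{y_i}\),
inverted in closed form; a block whose determinant falls below
\(10^{-12}\) of its mean-eigenvalue cube is reported as singular with its
pair index). The 6×6 system is solved by a rank-revealing QR so that
degenerate geometry (collinear points) is detected rather than silently
fit. The update applies the **Rodrigues** rotation of \(\Delta\alpha\) —
not \(I + \mathrm{skew}(\Delta\alpha)\) — so the rotation stays exactly
orthonormal at every iteration, which is what keeps the solver stable
under misalignments up to 180°. No damping or line search is added: the
method is plain Gauss-Newton with the covariances re-rotated each
iteration, and the test suite monitors the cost sequence (observed
increases on benchmark-style trials are round-off-level, below \(10^{-4}\)
relative, at the converged plateau).

Two threshold sets are exposed because they serve different roles: the
standalone benchmark solver defaults to 0.0001 mm / 0.0001° with a cap of
60 iterations (the cap doubling as the instability counter), while the
GTLS solve inside the IMLP loop uses 0.001 mm / 0.001°, matching the
outer loop's own termination scale. The rotation-only variant
(`register_gtls_rotation_only()`) restricts \(\Delta p\) to
\(\Delta\alpha\); its isotropic closed-form counterpart takes the SVD of
the cross-covariance about the **origin** (translation is known to be
zero, so centering would discard information).

## Outer-loop termination

The loop stops when both the rotation change (norm of the Rodrigues
vector of \(R_{k+1} R_k^\top\)) and the translation change stay below
`rot_thresh`/`trans_thresh` (defaults 0.001° / 0.001 mm) for **two
consecutive iterations**, at `max_iter` (default 100), or when cost
cycling is detected: the registration-phase cost increasing twice within
a four-iteration window with the two post-increase costs equal within
`cycle_tol` (relative, default \(10^{-4}\) — the magnitude of "a small
tolerance" was our choice). On a cycle the transform of the last
cost-decreasing iteration is returned. Because the noise models change
between iterations, no convergence guarantee exists; on smooth,
nearly-symmetric synthetic shapes the transform change can decay slowly
and reach the iteration cap while the pose is already sub-millimeter
accurate — the history data frame records per-iteration cost,
\(\sigma^2\), outlier counts and transform deltas so such cases are
visible. The registration loops contain no randomness: identical inputs
give bit-identical histories, and all stochasticity lives in the
generators, seeded by the caller.

## What the synthetic generators emulate

`gen_experiment1_trial()` reproduces the corresponding-point-set
benchmark: 50 ground-truth points uniform in \([-100, 100]^3\) mm; two
noisy copies with zero-mean Gaussian noise of eigenvalues
\([0.5, 0.5, 2]\) mm² (or isotropic 0.25 mm² for the one-sided protocol);
a random misalignment — uniform magnitude in the bin times a uniform
random direction, and a uniform angle about a uniform random axis —
applied to the source set, rotating points and covariances together.
Each set draws **one** random covariance orientation shared by all its
points (`orientation = "per_set"`): the protocol specifies a different
covariance per point *set*, and this reading reproduces the published
registration errors, whereas fresh per-point orientations (available as
`"per_point"`) make the weighted solver measurably more accurate than
reported because every pair then carries independent directional
information. Random rotations come from normalized Gaussian quaternions
(uniform over SO(3)); the rotation axis is uniform on the sphere.

The registration error (RE) of a trial is the mean distance between the
un-noised correspondences after registration; the target registration
error (TRE) of a surface trial is the mean displacement of 100
independent validation samples under estimated vs. true transforms, with
TRE > 10 mm conventionally counted as a failure.

The surface benchmarks run on meshes generated in code
(`make_synthetic_mesh()`): subdivided icosahedra projected to spheres,
scaled to ellipsoids, or radially perturbed into bumpy spheres at the
~100 mm scale of anatomical shapes. These are *synthetic stand-ins* — the
original studies used hip and femur meshes that are external data — so
the mesh-based checks in this package are property-based: exactness of
the search, correctness of the noise cases (`noise_case()` tabulates the
nine surface-conditioned σ-pairs), outward-projected outliers at 10–20 mm
(`gen_outlier_points()`, outwardness defined by face winding), and the
*ordering* claim that IMLP's TRE beats standard ICP's under anisotropic
noise with 10% outliers over ≥100 paired trials. Passing them shows the
machinery is correct and the robustness mechanism effective on shapes of
this scale and curvature; it does not certify error magnitudes on real
anatomy, which depend on shape-specific self-similarity and segmentation
artifacts that spheres with smooth bumps do not exhibit.

Problem sizes used by the shipped tests and the acceptance script —
1000-trial bins for the corresponding-point benchmark, 10⁴-query search
equivalence sweeps, 10⁴-match chi-square calibration, and 100 paired
mesh trials at 100 + 10 points on 1280-face fixtures — were chosen to
keep every Monte-Carlo standard error well inside the tolerances being
asserted while completing in minutes on one CPU.

## Numerical conventions and edge cases

* Eigenvalues ascending everywhere; eigenvector columns paired by rank.
* Rotation logarithm via `atan2`, with the near-π branch recovering the
  axis from the symmetric part and fixing signs from the off-diagonals.
* Symmetric 3×3 inversions by closed-form adjugate (R and C++ sides share
  the layout and the singularity rule).
* Covariance CSV side-files accept 9-column row-major or 6-column
  upper-triangular rows, validated row-by-row as symmetric PSD; loaders
  never reorder points, so side-files pair by row index.
* Meshes: 1-based indices in memory, 0-based in files; mm units;
  right-handed frames; face winding defines outward normals; zero-area
  faces are dropped on construction with a warning; ASCII PLY/STL/OFF
  only (binary variants are out of scope).
* Degenerate triangles in `datum_best_point()` error; degenerate (rank
  < 2) point configurations error in the closed-form solver and surface
  as singular normal matrices in the GTLS solver.
* An all-outlier iteration aborts with a diagnostic rather than fitting
  an empty set; `outlier_mode = "discard"` requires at least three
  surviving matches.

## Known limitations

Like all ICP-family methods the algorithm is local: it needs an
initialization within the basin of the correct optimum, and none of the
global-search, multi-resolution or non-rigid extensions are in scope.
The compact (minimal-volume) node bound is not implemented; the two
implemented bounds only affect speed, never results. PD-tree
serialization is not provided — trees rebuild in milliseconds at these
sizes. Mesh I/O is deliberately minimal (ASCII, triangles only) rather
than a general geometry-processing layer.
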