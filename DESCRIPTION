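Package: imlp
Title: Iterative Most-Likely Point Registration of 3D Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rigid-body registration of 3D point clouds and triangle meshes
    under anisotropic Gaussian noise models. Implements the Iterative
    Most-Likely Point (IMLP) algorithm: probabilistic correspondence via a
    principal-direction (PD) tree search with ellipsoid bounds, generalized
    total-least-squares (GTLS) alignment of corresponding point sets by
    Gauss-Newton iteration, dynamic match-uncertainty estimation, and
    chi-square outlier handling. Includes standard ICP, the IMLP-CP and
    IMLP-MD match-criterion variants, readers and writers for PLY/STL/OFF
    meshes and covariance side-files, and synthetic benchmark generators
    for corresponding-point-set and surface registration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
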