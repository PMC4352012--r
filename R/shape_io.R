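#' Triangle mesh and point cloud containers
#'
#' Meshes store vertices (n x 3, mm) and faces (m x 3, 1-based vertex
#' indices); face winding defines the outward normal (right-handed).
#' Degenerate (zero-area) faces are dropped with a warning on
#' construction. Point clouds store points and optional unit normals.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `imlp_mesh`.
#' @export
imlp_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  areas <- face_areas(vertices, faces)
  if (any(areas <= 1e-12)) {
    warning("dropping ", sum(areas <= 1e-12), " degenerate (zero-area) faces")
    faces <- faces[areas > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "imlp_mesh")
}

#' @rdname imlp_mesh
#' @param points n x 3 numeric matrix (mm).
#' @param normals optional n x 3 matrix of unit normals.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (any(!is.finite(points))) stop("non-finite point coordinates")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(identical(dim(normals), dim(points)))
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("normals must be unit length")
  }
  structure(list(points = points, normals = normals),
            class = "imlp_pointcloud")
}

face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nx / sqrt(rowSums(nx^2))
}

#' @export
print.imlp_mesh <- function(x, ...) {
  cat("Mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' @export
print.imlp_pointcloud <- function(x, ...) {
  cat("Point cloud:", nrow(x$points), "points",
      if (!is.null(x$normals)) "(with normals)" else "", "\n")
  invisible(x)
}

#' Read / write triangle meshes (ASCII PLY, STL, OFF)
#'
#' Formats are recognized by file extension. Units are assumed to be mm
#' and indices are converted to the package's 1-based convention on load.
#' STL facet soups are welded: vertices closer than 1e-6 mm are merged.
#' Round trips preserve vertices and faces to float precision and never
#' reorder points.
#'
#' @param path file path ending in `.ply`, `.stl` or `.off`.
#' @return [read_mesh()]: an [imlp_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply_mesh(path),
         stl = read_stl_mesh(path),
         off = read_off_mesh(path),
         stop("unsupported mesh extension: .", ext))
}

#' @rdname read_mesh
#' @param mesh an [imlp_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "imlp_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh$vertices, mesh$faces, path),
         stl = write_stl(mesh, path),
         off = write_off(mesh, path),
         stop("unsupported mesh extension: .", ext))
  invisible(path)
}

read_ply_header <- function(lines) {
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("malformed PLY: missing 'ply' magic (line 1)")
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("malformed PLY: no end_header")
  if (!any(grepl("^format\\s+ascii", trimws(lines[2:endh]))))
    stop("only ASCII PLY is supported")
  elems <- list()
  for (i in 2:endh) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 3 && tok[1] == "element")
      elems[[tok[2]]] <- as.integer(tok[3])
  }
  list(end = endh, elements = elems)
}

read_ply_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- read_ply_header(lines)
  nv <- h$elements[["vertex"]]
  nf <- if ("face" %in% names(h$elements)) h$elements[["face"]] else 0L
  if (is.null(nv)) stop("malformed PLY: no vertex element")
  body <- lines[(h$end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("malformed PLY: expected ", nv + nf, " data lines, found ",
         length(body))
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vt, function(x) as.numeric(x[1:3]), numeric(3)))
  if (nf == 0) stop("PLY has no faces; use read_point_cloud() instead")
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(seq_along(ft), function(i) {
    x <- as.numeric(ft[[i]])
    if (x[1] != 3)
      stop("malformed PLY: non-triangular face at data line ", nv + i)
    x[2:4] + 1
  }, numeric(3)))
  imlp_mesh(V, F)
}

#' @rdname read_mesh
#' @details `read_point_cloud()` accepts a faceless (or faced) ASCII PLY
#'   or a CSV/whitespace table with columns x, y, z and optionally
#'   nx, ny, nz.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path, warn = FALSE)
    h <- read_ply_header(lines)
    nv <- h$elements[["vertex"]]
    body <- lines[(h$end + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    vals <- t(vapply(vt, function(x) {
      v <- as.numeric(x)
      length(v) <- 6
      v
    }, numeric(6)))
    norms <- if (all(is.finite(vals[, 4:6]))) vals[, 4:6, drop = FALSE] else NULL
    return(point_cloud(vals[, 1:3, drop = FALSE], norms))
  }
  tab <- utils::read.table(path, sep = ",", header = FALSE,
                           comment.char = "#")
  tab <- as.matrix(tab)
  if (ncol(tab) >= 6) point_cloud(tab[, 1:3], tab[, 4:6]) else
    point_cloud(tab[, 1:3])
}

#' @rdname read_mesh
#' @param cloud an [point_cloud()] object.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "imlp_pointcloud"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    write_ply(cloud$points, NULL, path, normals = cloud$normals)
  } else {
    tab <- if (is.null(cloud$normals)) cloud$points else
      cbind(cloud$points, cloud$normals)
    utils::write.table(tab, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

write_ply <- function(V, F, path, normals = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(normals))
    writeLines(c("property float nx", "property float ny",
                 "property float nz"), con)
  if (!is.null(F))
    writeLines(c(paste("element face", nrow(F)),
                 "property list uchar int vertex_indices"), con)
  writeLines("end_header", con)
  vv <- if (is.null(normals)) V else cbind(V, normals)
  writeLines(apply(format(vv, digits = 17, scientific = FALSE, trim = TRUE),
                   1, paste, collapse = " "), con)
  if (!is.null(F))
    writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
}

read_off_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (trimws(lines[1]) != "OFF") stop("malformed OFF: missing magic (line 1)")
  cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  vt <- strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+")
  V <- t(vapply(vt, function(x) as.numeric(x[1:3]), numeric(3)))
  ft <- strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(ft, function(x) as.numeric(x[2:4]) + 1, numeric(3)))
  imlp_mesh(V, F)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF",
               paste(nrow(mesh$vertices), nrow(mesh$faces), 0)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, scientific = FALSE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  F <- mesh$faces
  writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
}

read_stl_mesh <- function(path, weld_tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported (missing 'solid' on line 1)")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0)
    stop("malformed STL: vertex count not a multiple of 3")
  P <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  # weld duplicated corner vertices within tolerance
  key <- apply(round(P / weld_tol) * weld_tol, 1, paste, collapse = "_")
  uid <- !duplicated(key)
  V <- P[uid, , drop = FALSE]
  map <- match(key, key[uid])
  F <- matrix(map, ncol = 3, byrow = TRUE)
  imlp_mesh(V, F)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- face_normals(mesh$vertices, mesh$faces)
  writeLines("solid shape", con)
  for (i in seq_len(nrow(mesh$faces))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       N[i, 1], N[i, 2], N[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- mesh$vertices[mesh$faces[i, j], ]
      writeLines(sprintf("      vertex %.17g %.17g %.17g",
                         v[1], v[2], v[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid shape", con)
}

#' Convert a mesh to a point cloud of face centroids
#'
#' One point per face at the triangle centroid, with the unit face normal
#' attached. This is how a dense point-cloud target is derived from a mesh
#' when evaluating point-cloud registration.
#'
#' @param mesh an [imlp_mesh()].
#' @return A [point_cloud()] with normals.
#' @export
mesh_to_point_cloud <- function(mesh) {
  stopifnot(inherits(mesh, "imlp_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  P <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  point_cloud(P, face_normals(V, F))
}

#' Read / write per-point covariance side-files
#'
#' CSV with one row per point: either 9 columns (the full 3x3 matrix in
#' row-major order) or 6 columns (upper triangle `m11, m12, m13, m22,
#' m23, m33`). Rows pair with points by index; loaders never reorder.
#' Each row is validated as symmetric positive semidefinite.
#'
#' @param path CSV file path.
#' @param n expected number of rows (points).
#' @return A list of 3x3 covariance matrices.
#' @export
read_covariances <- function(path, n) {
  tab <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  if (nrow(tab) != n)
    stop("covariance file has ", nrow(tab), " rows, expected ", n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- as.numeric(tab[i, ])
    M <- if (ncol(tab) == 9) {
      matrix(r, 3, 3, byrow = TRUE)
    } else if (ncol(tab) == 6) {
      matrix(c(r[1], r[2], r[3],
               r[2], r[4], r[5],
               r[3], r[5], r[6]), 3, 3)
    } else stop("covariance file must have 6 or 9 columns")
    if (max(abs(M - t(M))) > 1e-9)
      stop("asymmetric covariance at row ", i)
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(1, max(abs(ev))))
      stop("negative eigenvalue in covariance at row ", i)
    out[[i]] <- (M + t(M)) / 2
  }
  out
}

#' @rdname read_covariances
#' @param covs list of 3x3 matrices (or a 3x3xn array).
#' @export
write_covariances <- function(covs, path) {
  if (is.array(covs) && length(dim(covs)) == 3)
    covs <- lapply(seq_len(dim(covs)[3]), function(i) covs[, , i])
  rows <- t(vapply(covs, function(M) as.numeric(t(M)), numeric(9)))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' The transform is stored as a 4x4 homogeneous matrix in row-major order
#' under the key `matrix`. Reading validates the rotation block
#' (orthonormal, det +1); scaled or sheared matrices are rejected.
#'
#' @param T_ a [rigid_transform()].
#' @param path JSON file path.
#' @export
write_transform <- function(T_, path) {
  H <- rbind(cbind(T_$R, T_$t), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- obj$matrix
  if (!is.matrix(H)) H <- matrix(as.numeric(H), 4, 4, byrow = TRUE)
  storage.mode(H) <- "double"
  if (any(abs(H[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("not a homogeneous rigid transform (last row)")
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}
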