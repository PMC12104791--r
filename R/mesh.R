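# Triangle mesh container. Vertices are an n x 3 numeric matrix (mm, patient
# frame); faces an m x 3 integer matrix of 1-based vertex indices.

#' Construct and validate a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param validate run invariant checks (finite coordinates, >= 4 vertices and
#'   faces, indices in range, no degenerate faces).
#' @return object of class `leg_mesh`.
#' @export
leg_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  colnames(vertices) <- c("x", "y", "z")
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces), class = "leg_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @rdname leg_mesh
#' @param mesh a `leg_mesh`.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (ncol(v) != 3 || ncol(f) != 3) {
    stop_legalign("mesh must have 3-column vertex and face matrices",
                  "legalign_validation_error")
  }
  if (!all(is.finite(v))) {
    stop_legalign("mesh has non-finite vertex coordinates", "legalign_validation_error")
  }
  if (nrow(v) < 4 || nrow(f) < 4) {
    stop_legalign("mesh must have at least 4 vertices and 4 faces",
                  "legalign_validation_error")
  }
  if (min(f) < 1 || max(f) > nrow(v)) {
    bad <- which(apply(f, 1, function(r) any(r < 1 | r > nrow(v))))[1]
    stop_legalign(sprintf("face %d references a vertex index out of range", bad),
                  "legalign_validation_error")
  }
  same <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(same)) {
    stop_legalign(sprintf("face %d is degenerate (repeated vertex)", which(same)[1]),
                  "legalign_validation_error")
  }
  areas <- face_areas(mesh)
  if (any(areas <= 1e-12)) {
    stop_legalign(sprintf("face %d is degenerate (area <= 1e-12 mm^2)",
                          which(areas <= 1e-12)[1]),
                  "legalign_validation_error")
  }
  invisible(mesh)
}

#' Per-face areas, centroids and normals
#'
#' @param mesh a [leg_mesh()].
#' @return `face_areas`: numeric vector (mm^2); `face_centroids`: m x 3 matrix;
#'   `face_normals`: m x 3 matrix of unit outward normals (winding order).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# Area-weighted vertex normals (for noise displacement along the surface).
# Vertices not used by any face get a zero normal.
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  nv <- nrow(mesh$vertices)
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  vn <- matrix(0, nv, 3)
  vn[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(vn^2))
  nz <- len > 1e-12
  vn[nz, ] <- vn[nz, ] / len[nz]
  vn
}

#' Merge duplicate vertices
#'
#' Vertices closer than `eps` (snapped to an `eps` grid) are merged and face
#' indices remapped; faces collapsing to fewer than three distinct vertices
#' are dropped.
#'
#' @param mesh a [leg_mesh()].
#' @param eps merge tolerance in mm.
#' @return a `leg_mesh` with merged vertices.
#' @export
merge_vertices <- function(mesh, eps = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / eps), round(v[, 2] / eps), round(v[, 3] / eps))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  out <- leg_mesh(newv, newf[keep, , drop = FALSE], validate = FALSE)
  attr(out, "face_map") <- which(keep)  # old face index for each retained face
  out
}

# Apply a rigid transform to a mesh.
transform_mesh <- function(mesh, tf) {
  leg_mesh(rigid_apply_points(tf, mesh$vertices), mesh$faces, validate = FALSE)
}

#' @export
print.leg_mesh <- function(x, ...) {
  cat(sprintf("<leg_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(face_areas(x))))
  invisible(x)
}
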