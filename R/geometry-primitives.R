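# Low-level vector / line / plane primitives shared by every construction.
# Points are length-3 numeric vectors in millimetres; directions are unit
# vectors. Point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v^2))

#' Normalize a 3-vector to unit length
#' @param v numeric length-3 vector.
#' @param tol vectors shorter than `tol` raise a degeneracy error.
#' @return unit-length numeric vector.
#' @keywords internal
unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    stop_legalign("cannot normalize a (near-)zero vector", "legalign_degeneracy_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a 3D line
#'
#' A line is stored as a point on the line plus a unit direction.
#'
#' @param point numeric length-3 point on the line (mm).
#' @param direction numeric length-3 direction; normalized on construction.
#' @return object of class `line3`.
#' @export
line3 <- function(point, direction) {
  stopifnot(length(point) == 3, length(direction) == 3,
            all(is.finite(point)), all(is.finite(direction)))
  structure(list(point = as.numeric(point), direction = unitize(as.numeric(direction))),
            class = "line3")
}

#' Construct a 3D plane
#'
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal; normalized on construction.
#' @param rms_mm root-mean-square residual of the generating fit (0 for
#'   constructed planes).
#' @return object of class `plane3`.
#' @export
plane3 <- function(point, normal, rms_mm = 0) {
  stopifnot(length(point) == 3, length(normal) == 3, rms_mm >= 0)
  structure(list(point = as.numeric(point), normal = unitize(as.numeric(normal)),
                 rms_mm = as.numeric(rms_mm)),
            class = "plane3")
}

#' Project a point onto a plane along a direction
#'
#' Solves `p + t d` lying on the plane. Used to realize "projected on the
#' axial plane along the direction of the mechanical axis" constructions.
#'
#' @param p numeric length-3 point.
#' @param plane a [plane3()].
#' @param direction numeric length-3 projection direction.
#' @return numeric length-3 projected point.
#' @export
project_point_along <- function(p, plane, direction) {
  d <- unitize(direction)
  denom <- sum(d * plane$normal)
  if (abs(denom) <= 1e-9) {
    stop_legalign("projection direction is parallel to the plane",
                  "legalign_projection_error")
  }
  t <- sum((plane$point - p) * plane$normal) / denom
  p + t * d
}

#' Project a direction onto a plane
#'
#' Removes the component along `normal` and renormalizes.
#'
#' @param d numeric length-3 direction.
#' @param normal numeric length-3 plane normal.
#' @return unit direction lying in the plane.
#' @export
project_direction_onto_plane <- function(d, normal) {
  n <- unitize(normal)
  du <- unitize(d)
  if (acos(pmin(1, abs(sum(du * n)))) <= 1e-6) {
    stop_legalign("direction is parallel to the plane normal; projection degenerate",
                  "legalign_projection_error")
  }
  unitize(du - sum(du * n) * n)
}

#' Signed in-plane angle between two directions
#'
#' Both directions are projected into the plane with normal `plane_normal`;
#' the turn from the first to the second, taken clockwise when viewed along
#' the normal, is returned mapped to (0, 360]. Identical projections map to
#' 360 (a full turn); callers reduce modulo 360 where 0 is intended. Clinical
#' medial/lateral/posterior angle selection is layered on top by the
#' alignment functions.
#'
#' @param a,b numeric length-3 directions.
#' @param plane_normal numeric length-3 plane normal.
#' @return angle in degrees in (0, 360].
#' @export
angle_in_plane <- function(a, b, plane_normal) {
  n <- unitize(plane_normal)
  pa <- project_direction_onto_plane(a, n)
  pb <- project_direction_onto_plane(b, n)
  ang <- atan2(sum(cross3(pb, pa) * n), sum(pa * pb)) * 180 / pi
  ang <- ang %% 360
  if (ang <= 0) ang <- ang + 360
  ang
}

# Unsigned angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  ua <- unitize(a); ub <- unitize(b)
  2 * atan2(vnorm(ua - ub), vnorm(ua + ub)) * 180 / pi
}

# Direction of the intersection line of two planes.
plane_plane_intersection_dir <- function(plane_a, plane_b, min_dihedral_deg = 0.1) {
  d <- cross3(plane_a$normal, plane_b$normal)
  if (vnorm(d) < sin(min_dihedral_deg * pi / 180)) {
    stop_legalign("planes are nearly parallel; intersection line ill-defined",
                  "legalign_degeneracy_error")
  }
  unitize(d)
}

#' Intersect a line with a triangle mesh
#'
#' Vectorized Moller-Trumbore intersection of an infinite line with every
#' triangle of `mesh` (optionally restricted to `face_subset`). Hits are
#' deduplicated within `eps` mm and sorted by the line parameter, so a line
#' passing through a shared edge or vertex yields a single point.
#'
#' @param line a [line3()].
#' @param mesh a [leg_mesh()].
#' @param face_subset optional integer vector of 1-based face indices.
#' @param eps deduplication tolerance in mm.
#' @return matrix with columns `x`, `y`, `z` (possibly 0 rows), ordered along
#'   the line; attribute `t` carries the line parameters.
#' @export
line_mesh_intersections <- function(line, mesh, face_subset = NULL, eps = 1e-6) {
  faces <- mesh$faces
  if (!is.null(face_subset)) faces <- faces[face_subset, , drop = FALSE]
  if (nrow(faces) == 0) {
    out <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    attr(out, "t") <- numeric(0)
    return(out)
  }
  v  <- mesh$vertices
  p0 <- v[faces[, 1], , drop = FALSE]
  e1 <- v[faces[, 2], , drop = FALSE] - p0
  e2 <- v[faces[, 3], , drop = FALSE] - p0
  d  <- line$direction
  o  <- line$point
  # h = d x e2, row-wise
  h1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
  h2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
  h3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
  a  <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > 1e-14
  s1 <- o[1] - p0[, 1]; s2 <- o[2] - p0[, 2]; s3 <- o[3] - p0[, 3]
  u  <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  # q = s x e1
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  vv <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / a
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  bt <- 1e-10  # barycentric slack so edge/vertex grazes register on all faces
  hit <- ok & u >= -bt & vv >= -bt & (u + vv) <= 1 + bt & is.finite(tt)
  tt  <- tt[hit]
  if (length(tt) == 0) {
    out <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    attr(out, "t") <- numeric(0)
    return(out)
  }
  tt <- sort(tt)
  keep <- c(TRUE, diff(tt) > eps)
  tt <- tt[keep]
  pts <- t(vapply(tt, function(ti) o + ti * d, numeric(3)))
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "t") <- tt
  pts
}

# --- rigid transforms -------------------------------------------------------

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle_rad) {
  a <- unitize(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)  # column-major: K %*% v = a x v
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# A rigid transform is list(R = 3x3, t = length-3): x -> R x + t.
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  list(R = R, t = as.numeric(t))
}

rigid_apply_points <- function(tf, pts) {
  if (is.null(dim(pts))) return(as.numeric(tf$R %*% pts + tf$t))
  sweep(pts %*% t(tf$R), 2, -tf$t)
}

rigid_compose <- function(tf2, tf1) {  # applies tf1 first, then tf2
  rigid_transform(tf2$R %*% tf1$R, as.numeric(tf2$R %*% tf1$t) + tf2$t)
}

# Rotation about an axis through a point (not the origin).
rigid_rotation_about_line <- function(point, axis, angle_rad) {
  R <- rotation_about_axis(axis, angle_rad)
  rigid_transform(R, as.numeric(point - R %*% point))
}

rigid_apply_line <- function(tf, line) {
  line3(rigid_apply_points(tf, line$point), as.numeric(tf$R %*% line$direction))
}

rigid_apply_plane <- function(tf, plane) {
  plane3(rigid_apply_points(tf, plane$point), as.numeric(tf$R %*% plane$normal),
         plane$rms_mm)
}

# Random rotation via QR of a Gaussian matrix (uniform on SO(3) up to sign fix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
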