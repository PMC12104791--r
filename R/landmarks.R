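# Consensus joint centres and central medial-lateral axes.
#
# Hip:   centre of a geometric sphere fit to the femoral head surface.
# Knee (femoral): condylar cylinder axis intersected with the femur; midpoint
#        of the two extreme intersections.
# Knee (tibial): midpoint of the two plateau area-weighted centroids.
# Ankle: single pooled area-weighted centroid of plafond + both malleolar
#        facets (pooled, not midpoint-of-centroids).

#' Hip (proximal femoral) joint centre
#'
#' Centre of the geometric sphere fit to all available femoral-head surface
#' data (area-weighted face centroids).
#'
#' @param femur a FEMUR [bone_model()].
#' @return numeric length-3 centre; the full [fit_sphere()] result is attached
#'   as attribute `fit`.
#' @export
hip_center <- function(femur) {
  fit <- fit_sphere(region_points(femur, "FEMORAL_HEAD"))
  structure(fit$center, fit = fit)
}

# Cylinder fit to the union of both condyle regions.
condylar_cylinder <- function(femur) {
  m <- region_points(femur, "MEDIAL_FEMORAL_CONDYLE")
  l <- region_points(femur, "LATERAL_FEMORAL_CONDYLE")
  fit_cylinder(list(points = rbind(m$points, l$points),
                    weights = c(m$weights, l$weights)))
}

#' Distal femoral joint centre
#'
#' Fits a cylinder to the combined condylar articular surfaces, intersects its
#' central axis with the femur, and returns the midpoint of the two extreme
#' intersection points.
#'
#' @param femur a FEMUR [bone_model()].
#' @param scope intersect the axis with the whole bone (default) or with the
#'   condylar regions only.
#' @param cylinder optionally, a precomputed [fit_cylinder()] result.
#' @return numeric length-3 centre with attribute `fit` (the cylinder fit) and
#'   attribute `intersections` (the two extreme hits).
#' @export
distal_femoral_center <- function(femur, scope = c("bone", "condyle_regions"),
                                  cylinder = NULL) {
  scope <- match.arg(scope)
  fit <- cylinder %||% condylar_cylinder(femur)
  subset <- if (scope == "condyle_regions") {
    c(femur$regions$MEDIAL_FEMORAL_CONDYLE, femur$regions$LATERAL_FEMORAL_CONDYLE)
  }
  hits <- line_mesh_intersections(fit$axis, femur$mesh, face_subset = subset)
  if (nrow(hits) < 2) {
    stop_legalign(sprintf(
      "condylar axis intersects the femur at %d point(s); need at least 2",
      nrow(hits)), "legalign_construction_error")
  }
  ends <- hits[c(1, nrow(hits)), , drop = FALSE]
  structure(as.numeric(colMeans(ends)), fit = fit, intersections = ends)
}

#' Proximal tibial joint centre
#'
#' Midpoint of the two plateau area-weighted centroids.
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @return numeric length-3 centre.
#' @export
proximal_tibial_center <- function(tibfib) {
  cm <- surface_centroid(tibfib, "MEDIAL_TIBIAL_PLATEAU")
  cl <- surface_centroid(tibfib, "LATERAL_TIBIAL_PLATEAU")
  (cm + cl) / 2
}

#' Distal tibial/fibular (ankle) joint centre
#'
#' Single area-weighted centroid of the pooled plafond and malleolar articular
#' surfaces (pooled centroid, in contrast to the proximal tibia's
#' midpoint-of-centroids).
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @return numeric length-3 centre.
#' @export
distal_tibfib_center <- function(tibfib) {
  regs <- c("TIBIAL_PLAFOND", "MEDIAL_MALLEOLUS_FACET", "LATERAL_MALLEOLUS_FACET")
  pts <- lapply(regs, function(r) region_points(tibfib, r))
  p <- do.call(rbind, lapply(pts, `[[`, "points"))
  w <- unlist(lapply(pts, `[[`, "weights"))
  if (sum(w) <= 1e-12) {
    stop_legalign("ankle articular surfaces have zero total area",
                  "legalign_degeneracy_error")
  }
  as.numeric(colSums(p * w) / sum(w))
}

#' Neck-femur axis (proximal femoral medial-lateral axis)
#'
#' Line connecting the hip centre to the femoral-neck surface centroid,
#' directed from head towards neck.
#'
#' @param femur a FEMUR [bone_model()].
#' @param hip optionally, a precomputed [hip_center()].
#' @return a [line3()].
#' @export
neck_femur_axis <- function(femur, hip = NULL) {
  h <- as.numeric(hip %||% hip_center(femur))
  n <- surface_centroid(femur, "FEMORAL_NECK")
  if (vnorm(n - h) < 1) {
    stop_legalign("femoral neck centroid coincides with the hip centre",
                  "legalign_degeneracy_error")
  }
  line3(h, n - h)
}

# Orient a medial-lateral axis from the medial to the lateral structure.
# `right_hint` is the approximate patient-right direction; for a RIGHT leg
# medial-to-lateral points to patient right, for a LEFT leg to patient left.
orient_medial_to_lateral <- function(line, side, right_hint) {
  want <- if (side == "RIGHT") 1 else -1
  s <- sum(line$direction * right_hint)
  if (abs(s) < 1e-9) {
    stop_legalign("cannot orient medial-lateral axis: direction orthogonal to the right hint",
                  "legalign_degeneracy_error")
  }
  if (sign(s) != want) line3(line$point, -line$direction) else line
}

#' Central medial-lateral axis of the distal femur
#'
#' The condylar cylinder-fit axis, oriented medial to lateral using the side
#' flag and orientation hint.
#'
#' @param femur a FEMUR [bone_model()].
#' @param right_hint approximate patient-right direction.
#' @param cylinder optionally, a precomputed [fit_cylinder()] result.
#' @return a [line3()] with attribute `fit`.
#' @export
central_ml_axis_distal_femur <- function(femur, right_hint = c(1, 0, 0),
                                         cylinder = NULL) {
  fit <- cylinder %||% condylar_cylinder(femur)
  structure(orient_medial_to_lateral(fit$axis, femur$side, right_hint), fit = fit)
}

#' Central medial-lateral axis of the proximal tibia
#'
#' Line through the two plateau centroids, oriented medial to lateral.
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @param right_hint approximate patient-right direction.
#' @return a [line3()].
#' @export
central_ml_axis_proximal_tibia <- function(tibfib, right_hint = c(1, 0, 0)) {
  cm <- surface_centroid(tibfib, "MEDIAL_TIBIAL_PLATEAU")
  cl <- surface_centroid(tibfib, "LATERAL_TIBIAL_PLATEAU")
  if (vnorm(cl - cm) < 1) {
    stop_legalign("plateau centroids nearly coincide", "legalign_degeneracy_error")
  }
  orient_medial_to_lateral(line3((cm + cl) / 2, cl - cm), tibfib$side, right_hint)
}

#' Intermalleolar axis
#'
#' Line through the medial and lateral malleolar facet centroids, oriented
#' medial to lateral.
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @param right_hint approximate patient-right direction.
#' @return a [line3()].
#' @export
intermalleolar_axis <- function(tibfib, right_hint = c(1, 0, 0)) {
  cm <- surface_centroid(tibfib, "MEDIAL_MALLEOLUS_FACET")
  cl <- surface_centroid(tibfib, "LATERAL_MALLEOLUS_FACET")
  if (vnorm(cl - cm) < 1) {
    stop_legalign("malleolar centroids nearly coincide", "legalign_degeneracy_error")
  }
  orient_medial_to_lateral(line3((cm + cl) / 2, cl - cm), tibfib$side, right_hint)
}
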