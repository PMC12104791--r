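# Anatomical coordinate systems. Every frame is a right-handed orthonormal
# triad: x medial-lateral pointing to the patient's right, y posterior-
# anterior pointing anteriorly, z distal-proximal pointing cranially.

#' Construct a coordinate frame
#'
#' @param origin numeric length-3 origin (mm).
#' @param x,z numeric length-3 axes; `z` is normalized, `x` is orthogonalized
#'   against `z` and normalized, `y = z x x`.
#' @return object of class `leg_frame` with `origin`, `x`, `y`, `z`.
#' @export
leg_frame_new <- function(origin, x, z) {
  z <- unitize(z)
  x <- x - sum(x * z) * z
  if (vnorm(x) < 1e-9) {
    stop_legalign("frame x-axis is parallel to z-axis", "legalign_degeneracy_error")
  }
  x <- unitize(x)
  y <- cross3(z, x)
  structure(list(origin = as.numeric(origin), x = x, y = y, z = z),
            class = "leg_frame")
}

#' @export
print.leg_frame <- function(x, ...) {
  cat(sprintf("<leg_frame> origin (%.2f, %.2f, %.2f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x", "y", "z")) {
    cat(sprintf("  %s: (% .4f, % .4f, % .4f)\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  invisible(x)
}

# Coordinates of points in a frame.
frame_coords <- function(frame, pts) {
  q <- sweep(as.matrix(pts), 2, frame$origin)
  q %*% cbind(frame$x, frame$y, frame$z)
}

# The medial direction within a frame, resolved from the side: x points to
# the patient's right, so medial is -x for a right leg, +x for a left leg.
frame_medial <- function(frame, side) {
  if (side == "RIGHT") -frame$x else frame$x
}

frame_lateral <- function(frame, side) -frame_medial(frame, side)

# Build a frame per the consensus recipe: z along the longitudinal axis
# (pointing cranially, resolved with the hint), x from the projected
# medial-lateral axis (sign fixed to patient right via the hint).
build_frame <- function(origin, longitudinal_dir, ml_dir, hint) {
  z <- unitize(longitudinal_dir)
  if (sum(z * hint[3, ]) < 0) z <- -z  # cranial
  ang <- angle_between(ml_dir, z)
  if (ang > 89.9 && ang < 90.1) {
    # fine: nearly orthogonal is the normal case
  } else if (ang < 0.1 || ang > 179.9) {
    stop_legalign("medial-lateral axis parallel to the longitudinal axis; frame degenerate",
                  "legalign_degeneracy_error")
  }
  x <- ml_dir - sum(ml_dir * z) * z
  if (vnorm(x) < 1e-9) {
    stop_legalign("medial-lateral axis projects to zero on the axial plane",
                  "legalign_degeneracy_error")
  }
  x <- unitize(x)
  if (sum(x * hint[1, ]) < 0) x <- -x  # patient right
  leg_frame_new(origin, x, z)
}

#' Femoral coordinate system
#'
#' Origin at the distal femoral joint centre; z parallel to the mechanical
#' femoral axis (cranial); x the condylar central medial-lateral axis
#' projected along z onto the femoral axial plane, pointing to the patient's
#' right; y orthogonal (anterior).
#'
#' @param femur a FEMUR [bone_model()].
#' @param hint orientation hint matrix (rows: right, anterior, cranial).
#' @param centers optional precomputed list with `hip`, `knee_femoral` and the
#'   condylar `cylinder` fit (as produced by [build_leg_assembly()]).
#' @return a `leg_frame`.
#' @export
build_femoral_frame <- function(femur, hint = diag(3), centers = NULL) {
  if (is.null(centers)) {
    cyl <- condylar_cylinder(femur)
    hip <- hip_center(femur)
    knee <- distal_femoral_center(femur, cylinder = cyl)
    centers <- list(hip = as.numeric(hip), knee_femoral = as.numeric(knee),
                    cylinder = cyl)
  }
  mfa <- centers$hip - centers$knee_femoral
  if (vnorm(mfa) < 10) {
    stop_legalign("mechanical femoral axis is shorter than 10 mm",
                  "legalign_degeneracy_error")
  }
  build_frame(centers$knee_femoral, mfa, centers$cylinder$axis$direction, hint)
}

#' Tibial/fibular coordinate system
#'
#' Origin at the proximal tibial joint centre; z parallel to the mechanical
#' tibial axis; x from the plateau-centroid medial-lateral axis projected on
#' the tibial axial plane.
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @param hint orientation hint matrix.
#' @param centers optional precomputed list with `knee_tibial`, `ankle` and
#'   `ml_axis`.
#' @return a `leg_frame`.
#' @export
build_tibial_frame <- function(tibfib, hint = diag(3), centers = NULL) {
  if (is.null(centers)) {
    centers <- list(knee_tibial = proximal_tibial_center(tibfib),
                    ankle = distal_tibfib_center(tibfib),
                    ml_axis = central_ml_axis_proximal_tibia(tibfib, hint[1, ]))
  }
  mta <- centers$knee_tibial - centers$ankle
  if (vnorm(mta) < 10) {
    stop_legalign("mechanical tibial axis is shorter than 10 mm",
                  "legalign_degeneracy_error")
  }
  build_frame(centers$knee_tibial, mta, centers$ml_axis$direction, hint)
}

#' Leg (combined) coordinate system
#'
#' Origin at the distal femoral joint centre; z parallel to the mechanical leg
#' axis (Mikulicz line, ankle to hip); x the condylar medial-lateral axis
#' projected along z on the leg axial plane.
#'
#' @param assembly a [build_leg_assembly()] result (or any list carrying
#'   `centers$hip`, `centers$ankle`, `centers$knee_femoral`,
#'   `ml_axes$distal_femoral` and `hint`).
#' @param min_leg_length_mm sanity guard on the hip-ankle distance.
#' @return a `leg_frame`.
#' @export
build_leg_frame <- function(assembly, min_leg_length_mm = 100) {
  mla <- assembly$centers$hip - assembly$centers$ankle
  if (vnorm(mla) < min_leg_length_mm) {
    stop_legalign(sprintf("hip-ankle distance %.1f mm below sanity guard %.0f mm",
                          vnorm(mla), min_leg_length_mm),
                  "legalign_degeneracy_error")
  }
  build_frame(assembly$centers$knee_femoral, mla,
              assembly$ml_axes$distal_femoral$direction, assembly$hint)
}

# --- leg assembly -----------------------------------------------------------

# Compute all centres, axes and frames for one leg. The femoral fits are done
# once and reused; tibial quantities are cheap and recomputed by
# virtual_extend after each rotation.
tibial_measures <- function(tibfib, hint) {
  knee_tibial <- proximal_tibial_center(tibfib)
  ankle <- distal_tibfib_center(tibfib)
  ml <- central_ml_axis_proximal_tibia(tibfib, hint[1, ])
  ima <- intermalleolar_axis(tibfib, hint[1, ])
  list(knee_tibial = knee_tibial, ankle = ankle, ml_axis = ml, intermalleolar = ima)
}

#' Assemble a leg: centres, mechanical axes, frames, extension residual
#'
#' @param femur a FEMUR [bone_model()].
#' @param tibfib a TIBIA_FIBULA [bone_model()] of the same side.
#' @param config a [legalign_config()].
#' @return object of class `leg_assembly` with `centers`, `axes` (mFA, mTA,
#'   mLA as [line3()], directions stored pointing proximally), `ml_axes`,
#'   `frames` (femoral, tibial, leg), `extension_residual_deg`,
#'   `fit_residuals` and the input models.
#' @export
build_leg_assembly <- function(femur, tibfib, config = legalign_config()) {
  config <- as_legalign_config(config)
  if (femur$bone != "FEMUR" || tibfib$bone != "TIBIA_FIBULA") {
    stop_legalign("build_leg_assembly needs one FEMUR and one TIBIA_FIBULA model",
                  "legalign_validation_error")
  }
  if (femur$side != tibfib$side) {
    stop_legalign("femur and tibia/fibula models are from different sides",
                  "legalign_validation_error")
  }
  hint <- config$orientation.hint

  hip_fit <- fit_sphere(region_points(femur, "FEMORAL_HEAD"),
                        tol = config$fit.tolerance, max_iter = config$fit.max_iter)
  hip <- hip_fit$center
  m <- region_points(femur, "MEDIAL_FEMORAL_CONDYLE")
  l <- region_points(femur, "LATERAL_FEMORAL_CONDYLE")
  cyl <- fit_cylinder(list(points = rbind(m$points, l$points),
                           weights = c(m$weights, l$weights)),
                      tol = config$fit.tolerance, max_iter = config$fit.max_iter)
  knee_femoral <- distal_femoral_center(
    femur, scope = config$center.femoral_intersection_scope, cylinder = cyl)
  nfa <- neck_femur_axis(femur, hip = hip)
  dml <- central_ml_axis_distal_femur(femur, hint[1, ], cylinder = cyl)

  tm <- tibial_measures(tibfib, hint)

  assembly <- structure(list(
    femur = femur, tibfib = tibfib, side = femur$side, hint = hint,
    config = config,
    centers = list(hip = as.numeric(hip),
                   knee_femoral = as.numeric(knee_femoral),
                   knee_tibial = tm$knee_tibial,
                   ankle = tm$ankle,
                   neck_center = surface_centroid(femur, "FEMORAL_NECK"),
                   cylinder = cyl),
    ml_axes = list(distal_femoral = structure(dml, fit = NULL),
                   proximal_tibial = tm$ml_axis,
                   neck_femur = nfa,
                   intermalleolar = tm$intermalleolar),
    fit_residuals = c(femoral_head_sphere = hip_fit$rms_mm,
                      condylar_cylinder = cyl$rms_mm),
    extension_transform = rigid_transform()
  ), class = "leg_assembly")

  refresh_assembly_frames(assembly)
}

# (Re)build mechanical axes, frames and the extension residual from the
# current centres. Used after every virtual-extension rotation.
refresh_assembly_frames <- function(assembly) {
  ctr <- assembly$centers
  assembly$axes <- list(
    mFA = line3(ctr$knee_femoral, ctr$hip - ctr$knee_femoral),
    mTA = line3(ctr$ankle, ctr$knee_tibial - ctr$ankle),
    mLA = line3(ctr$ankle, ctr$hip - ctr$ankle)
  )
  fem_centers <- list(hip = ctr$hip, knee_femoral = ctr$knee_femoral,
                      cylinder = ctr$cylinder)
  tib_centers <- list(knee_tibial = ctr$knee_tibial, ankle = ctr$ankle,
                      ml_axis = assembly$ml_axes$proximal_tibial)
  assembly$frames <- list(
    femoral = build_femoral_frame(assembly$femur, assembly$hint, fem_centers),
    tibial = build_tibial_frame(assembly$tibfib, assembly$hint, tib_centers)
  )
  assembly$frames$leg <- build_leg_frame(assembly)
  assembly$extension_residual_deg <- extension_residual(assembly)
  assembly
}

#' Knee-extension residual
#'
#' Absolute angle between the projections of the mechanical femoral and tibial
#' axes onto the sagittal plane of the leg coordinate system (normal = leg x).
#' Zero means the axes are parallel in that plane, i.e. the knee is extended;
#' a pure coronal deformity does not register.
#'
#' @param assembly a [build_leg_assembly()] result.
#' @return residual in degrees, in `[0, 90)`.
#' @export
extension_residual <- function(assembly) {
  abs(sagittal_flexion_angle(assembly))
}

# Signed sagittal-plane angle from the projected mTA to the projected mFA
# (both proximal-pointing) about the leg x-axis. virtual_extend rotates the
# tibia by this amount about the condylar axis.
sagittal_flexion_angle <- function(assembly) {
  xn <- assembly$frames$leg$x
  pf <- project_direction_onto_plane(assembly$axes$mFA$direction, xn)
  pt <- project_direction_onto_plane(assembly$axes$mTA$direction, xn)
  atan2(sum(cross3(pt, pf) * xn), sum(pt * pf)) * 180 / pi
}

#' Virtually extend the knee
#'
#' Rigidly rotates the tibia/fibula about the condylar cylinder axis (the only
#' consensus-derived medial-lateral knee axis) by the sagittal-plane residual,
#' recomputing the ankle centre, leg frame and residual each iteration until
#' the residual drops below `tol_deg`. The femur never moves.
#'
#' @param assembly a [build_leg_assembly()] result.
#' @param tol_deg convergence tolerance in degrees (default from config).
#' @param max_iter iteration cap (default from config).
#' @return a new `leg_assembly`, with the cumulative rigid transform recorded
#'   in `extension_transform` and the residual trajectory in
#'   `extension_trajectory_deg`.
#' @export
virtual_extend <- function(assembly, tol_deg = NULL, max_iter = NULL) {
  cfg <- assembly$config
  tol_deg <- tol_deg %||% cfg$extension.tolerance_deg
  max_iter <- max_iter %||% cfg$extension.max_iter
  flex_axis <- assembly$centers$cylinder$axis
  trajectory <- assembly$extension_residual_deg
  if (assembly$extension_residual_deg <= tol_deg) {
    assembly$extension_trajectory_deg <- trajectory
    return(assembly)
  }
  total <- assembly$extension_transform
  for (i in seq_len(max_iter)) {
    delta <- sagittal_flexion_angle(assembly)  # rotate mTA towards mFA
    sgn <- sign(sum(flex_axis$direction * assembly$frames$leg$x))
    if (sgn == 0) {
      stop_legalign("flexion axis orthogonal to the leg x-axis; cannot extend",
                    "legalign_extension_error")
    }
    tf <- rigid_rotation_about_line(flex_axis$point, flex_axis$direction,
                                    sgn * delta * pi / 180)
    assembly$tibfib <- transform_bone_model(assembly$tibfib, tf)
    total <- rigid_compose(tf, total)
    tm <- tibial_measures(assembly$tibfib, assembly$hint)
    assembly$centers$knee_tibial <- tm$knee_tibial
    assembly$centers$ankle <- tm$ankle
    assembly$ml_axes$proximal_tibial <- tm$ml_axis
    assembly$ml_axes$intermalleolar <- tm$intermalleolar
    assembly <- refresh_assembly_frames(assembly)
    trajectory <- c(trajectory, assembly$extension_residual_deg)
    if (assembly$extension_residual_deg <= tol_deg) {
      assembly$extension_transform <- total
      assembly$extension_trajectory_deg <- trajectory
      return(assembly)
    }
  }
  stop_legalign(
    sprintf("virtual extension did not converge below %.3g deg in %d iterations (trajectory: %s)",
            tol_deg, max_iter, paste(sprintf("%.3f", trajectory), collapse = " -> ")),
    "legalign_extension_error", trajectory = trajectory)
}

#' @export
print.leg_assembly <- function(x, ...) {
  cat(sprintf("<leg_assembly> side %s, extension residual %.3f deg\n",
              x$side, x$extension_residual_deg))
  cat(sprintf("  hip (%.1f, %.1f, %.1f)  knee (%.1f, %.1f, %.1f)  ankle (%.1f, %.1f, %.1f)\n",
              x$centers$hip[1], x$centers$hip[2], x$centers$hip[3],
              x$centers$knee_femoral[1], x$centers$knee_femoral[2], x$centers$knee_femoral[3],
              x$centers$ankle[1], x$centers$ankle[2], x$centers$ankle[3]))
  invisible(x)
}
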