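# Joint orientations and the eight consensus alignment angles.
#
# Sign conventions (documented in the methods vignette):
#   HKAA   medial angle between projected mFA and mTA in the leg coronal
#          plane; 180 = straight, varus < 180, valgus > 180.
#   mLDFA  lateral angle between the proximal-pointing projected mFA and the
#          lateral-pointing condylar tangent, leg coronal plane; varus > 90.
#   mMPTA  medial angle between the proximal-pointing projected mTA and the
#          medial-pointing PTJ/coronal intersection; varus < 90.
#   mPDFA / mMPPTA / mLPPTA  posterior angle between the distal-pointing
#          projected mechanical axis and the posterior-pointing intersection
#          of the joint plane with the sagittal plane; posterior slope < 90.
#   FVA / TTA  acute axial-plane angles between medial-to-lateral axes;
#          anteversion / external torsion when the projected medial-to-lateral
#          neck (or intermalleolar) axis has a posterior component in its
#          reference frame.

#' Condylar tangent line (distal femoral joint orientation, DFJ)
#'
#' For each condyle, the most distal surface point relative to the reference
#' frame (minimum z); ties within `tie_eps` mm are averaged into one point.
#' The returned line joins the two points, directed medial to lateral.
#'
#' @param femur a FEMUR [bone_model()].
#' @param ref_frame reference `leg_frame` (the leg frame for coronal use).
#' @param tie_eps tie tolerance in mm.
#' @return a [line3()] with attribute `points` (2 x 3: medial, lateral).
#' @export
condylar_tangent_line <- function(femur, ref_frame, tie_eps = 1e-9) {
  pick <- function(region) {
    vix <- region_vertex_indices(femur, region)
    pts <- femur$mesh$vertices[vix, , drop = FALSE]
    z <- frame_coords(ref_frame, pts)[, 3]
    tie <- z <= min(z) + tie_eps
    colMeans(pts[tie, , drop = FALSE])
  }
  pm <- pick("MEDIAL_FEMORAL_CONDYLE")
  pl <- pick("LATERAL_FEMORAL_CONDYLE")
  if (vnorm(pl - pm) < 1) {
    stop_legalign("condylar most-distal points nearly coincide",
                  "legalign_degeneracy_error")
  }
  structure(line3(pm, pl - pm), points = rbind(medial = pm, lateral = pl))
}

#' Supracondylar-trochlear plane (SFJ)
#'
#' Default (`"three_point"`, the figure construction): one most-proximal
#' point per region (trochlea, medial condyle, lateral condyle; max z in
#' `ref_frame`, ties averaged), plane through the three points.
#' `"border_band"`: total-least-squares plane through the top 2% z-band of
#' each region (reading "most proximal borders" as border curves).
#' The normal is oriented into the +z hemisphere of the reference frame.
#'
#' @param femur a FEMUR [bone_model()].
#' @param ref_frame reference `leg_frame` (femoral frame).
#' @param mode `"three_point"` or `"border_band"`.
#' @param tie_eps tie tolerance in mm.
#' @return a [plane3()] with attribute `points` in three-point mode.
#' @export
supracondylar_plane <- function(femur, ref_frame,
                                mode = c("three_point", "border_band"),
                                tie_eps = 1e-9) {
  mode <- match.arg(mode)
  regions <- c("TROCHLEA", "MEDIAL_FEMORAL_CONDYLE", "LATERAL_FEMORAL_CONDYLE")
  if (mode == "three_point") {
    pts <- t(vapply(regions, function(region) {
      vix <- region_vertex_indices(femur, region)
      p <- femur$mesh$vertices[vix, , drop = FALSE]
      z <- frame_coords(ref_frame, p)[, 3]
      tie <- z >= max(z) - tie_eps
      colMeans(p[tie, , drop = FALSE])
    }, numeric(3)))
    n <- cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
    if (vnorm(n) < 1e-6) {
      stop_legalign("supracondylar points are collinear", "legalign_degeneracy_error")
    }
    n <- unitize(n)
    if (sum(n * ref_frame$z) < 0) n <- -n
    structure(plane3(colMeans(pts), n, 0), points = pts)
  } else {
    sel <- lapply(regions, function(region) {
      rp <- region_points(femur, region)
      z <- frame_coords(ref_frame, rp$points)[, 3]
      keep <- z >= max(z) - 0.02 * (max(z) - min(z)) - tie_eps
      list(points = rp$points[keep, , drop = FALSE], weights = rp$weights[keep])
    })
    fit_plane(list(points = do.call(rbind, lapply(sel, `[[`, "points")),
                   weights = unlist(lapply(sel, `[[`, "weights"))),
              orient_hint = ref_frame$z)
  }
}

#' Tibial plateau joint-orientation plane (PTJ)
#'
#' Area-weighted total-least-squares plane over the selected plateau
#' region(s); the normal is oriented proximally (towards the tibial +z).
#'
#' @param tibfib a TIBIA_FIBULA [bone_model()].
#' @param which `"MEDIAL"`, `"LATERAL"` or `"COMBINED"`.
#' @param proximal_hint direction whose hemisphere the normal should lie in
#'   (the tibial mechanical axis, pointing proximally).
#' @return a [plane3()].
#' @export
plateau_plane <- function(tibfib, which = c("COMBINED", "MEDIAL", "LATERAL"),
                          proximal_hint = c(0, 0, 1)) {
  which <- match.arg(which)
  regions <- switch(which,
                    MEDIAL = "MEDIAL_TIBIAL_PLATEAU",
                    LATERAL = "LATERAL_TIBIAL_PLATEAU",
                    COMBINED = c("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU"))
  pts <- lapply(regions, function(r) region_points(tibfib, r))
  fit_plane(list(points = do.call(rbind, lapply(pts, `[[`, "points")),
                 weights = unlist(lapply(pts, `[[`, "weights"))),
            orient_hint = proximal_hint)
}

#' Joint orientation set
#'
#' Computes DFJ, SFJ, the three plateau planes, NFA and the intermalleolar
#' axis for an assembly.
#'
#' @param assembly a [build_leg_assembly()] result.
#' @return list of class `joint_orientations`.
#' @export
joint_orientations <- function(assembly) {
  cfg <- assembly$config
  structure(list(
    DFJ = condylar_tangent_line(assembly$femur, assembly$frames$leg),
    SFJ = supracondylar_plane(assembly$femur, assembly$frames$femoral,
                              mode = cfg$sfj.mode),
    PTJ_medial = plateau_plane(assembly$tibfib, "MEDIAL",
                               proximal_hint = assembly$axes$mTA$direction),
    PTJ_lateral = plateau_plane(assembly$tibfib, "LATERAL",
                                proximal_hint = assembly$axes$mTA$direction),
    PTJ_combined = plateau_plane(assembly$tibfib, "COMBINED",
                                 proximal_hint = assembly$axes$mTA$direction),
    NFA = assembly$ml_axes$neck_femur,
    IMA = assembly$ml_axes$intermalleolar
  ), class = "joint_orientations")
}

# Orient `dir` (or its negation) so it points along `towards`.
orient_towards <- function(dir, towards) {
  if (sum(dir * towards) < 0) -dir else dir
}

#' Hip-knee-ankle angle (HKAA)
#'
#' Medial angle between the projections of the proximal-pointing mFA and
#' distal-pointing mTA on the leg coronal plane. 180 = straight; varus < 180.
#'
#' @param assembly a [build_leg_assembly()] result.
#' @param orientations optional [joint_orientations()] (unused, accepted for
#'   uniform calling).
#' @return angle in degrees.
#' @export
compute_hkaa <- function(assembly, orientations = NULL) {
  leg <- assembly$frames$leg
  f <- project_direction_onto_plane(assembly$axes$mFA$direction, leg$y)
  t <- project_direction_onto_plane(-assembly$axes$mTA$direction, leg$y)
  alpha <- angle_between(f, t)
  s <- f + t
  med <- sum(s * frame_medial(leg, assembly$side))
  if (med > 1e-12) alpha else 360 - alpha
}

#' Mechanical lateral distal femoral angle (mLDFA)
#'
#' Lateral angle between the projected proximal-pointing mFA and the
#' lateral-pointing condylar tangent (DFJ) in the leg coronal plane.
#'
#' @inheritParams compute_hkaa
#' @return angle in degrees (perpendicular construction = 90; varus > 90).
#' @export
compute_mldfa <- function(assembly, orientations = NULL) {
  orientations <- orientations %||% joint_orientations(assembly)
  leg <- assembly$frames$leg
  f <- project_direction_onto_plane(assembly$axes$mFA$direction, leg$y)
  dfj <- project_direction_onto_plane(
    orient_towards(orientations$DFJ$direction, frame_lateral(leg, assembly$side)),
    leg$y)
  angle_between(f, dfj)
}

#' Mechanical medial proximal tibial angle (mMPTA)
#'
#' The combined plateau plane is intersected with the leg coronal plane; the
#' angle on the medial side against the proximal-pointing projected mTA.
#'
#' @inheritParams compute_hkaa
#' @return angle in degrees (varus < 90).
#' @export
compute_mmpta <- function(assembly, orientations = NULL) {
  orientations <- orientations %||% joint_orientations(assembly)
  leg <- assembly$frames$leg
  coronal <- plane3(leg$origin, leg$y)
  jline <- plane_plane_intersection_dir(orientations$PTJ_combined, coronal)
  jline <- orient_towards(jline, frame_medial(leg, assembly$side))
  t <- project_direction_onto_plane(assembly$axes$mTA$direction, leg$y)
  angle_between(t, jline)
}

# Shared sagittal-plane posterior-angle rule: angle between the
# distal-pointing projected mechanical axis and the posterior-pointing
# intersection of the joint plane with the sagittal plane of `frame`.
sagittal_posterior_angle <- function(mech_dir_proximal, joint_plane, frame) {
  sagittal <- plane3(frame$origin, frame$x)
  jline <- plane_plane_intersection_dir(joint_plane, sagittal)
  jline <- orient_towards(jline, -frame$y)  # posterior
  d <- project_direction_onto_plane(-mech_dir_proximal, frame$x)
  angle_between(d, jline)
}

#' Mechanical posterior distal femoral angle (mPDFA)
#'
#' Posterior angle between the projected mFA and the intersection of the
#' supracondylar-trochlear plane with the femoral sagittal plane.
#'
#' @inheritParams compute_hkaa
#' @return angle in degrees (neutral construction = 90).
#' @export
compute_mpdfa <- function(assembly, orientations = NULL) {
  orientations <- orientations %||% joint_orientations(assembly)
  sagittal_posterior_angle(assembly$axes$mFA$direction, orientations$SFJ,
                           assembly$frames$femoral)
}

#' Medial and lateral posterior proximal tibial angles (mMPPTA, mLPPTA)
#'
#' Per-compartment plateau planes intersected with the tibial sagittal plane;
#' posterior angle against the projected mTA. A posterior slope of 7 degrees
#' yields 83.
#'
#' @inheritParams compute_hkaa
#' @return named numeric vector `c(mMPPTA, mLPPTA)` in degrees.
#' @export
compute_slope_angles <- function(assembly, orientations = NULL) {
  orientations <- orientations %||% joint_orientations(assembly)
  tib <- assembly$frames$tibial
  c(mMPPTA = sagittal_posterior_angle(assembly$axes$mTA$direction,
                                      orientations$PTJ_medial, tib),
    mLPPTA = sagittal_posterior_angle(assembly$axes$mTA$direction,
                                      orientations$PTJ_lateral, tib))
}

# Shared axial-plane acute-angle rule for version/torsion. `ml_ref` is the
# medial-to-lateral reference axis that defined the frame's x; `ml_other` the
# medial-to-lateral axis compared against it. The direction label comes from
# the anterior component of the projected `ml_other`: a posterior component
# means the structure it points to (neck, lateral malleolus) lies posteriorly,
# i.e. anteversion / external torsion. Side-invariant by construction.
axial_acute_angle <- function(ml_ref, ml_other, frame, labels) {
  a1 <- project_direction_onto_plane(ml_ref, frame$z)
  a2 <- project_direction_onto_plane(ml_other, frame$z)
  ang <- angle_between(a1, a2)
  if (ang > 90) ang <- 180 - ang
  label <- if (sum(a2 * frame$y) < 0) labels[1] else labels[2]
  list(angle = ang, direction = label)
}

#' Femoral version angle (FVA)
#'
#' Acute angle between the projections of the neck-femur axis and the
#' condylar central medial-lateral axis on the femoral axial plane, with an
#' anteversion/retroversion label.
#'
#' @inheritParams compute_hkaa
#' @return list with `angle` (degrees in `[0, 90]`) and `direction`
#'   (`"ANTEVERSION"` or `"RETROVERSION"`).
#' @export
compute_fva <- function(assembly, orientations = NULL) {
  axial_acute_angle(assembly$ml_axes$distal_femoral$direction,
                    assembly$ml_axes$neck_femur$direction,
                    assembly$frames$femoral,
                    c("ANTEVERSION", "RETROVERSION"))
}

#' Tibial torsion angle (TTA)
#'
#' Acute angle between the projections of the intermalleolar axis and the
#' proximal tibial central medial-lateral axis on the tibial axial plane,
#' with an external/internal label.
#'
#' @inheritParams compute_hkaa
#' @return list with `angle` (degrees in `[0, 90]`) and `direction`
#'   (`"EXTERNAL"` or `"INTERNAL"`).
#' @export
compute_tta <- function(assembly, orientations = NULL) {
  axial_acute_angle(assembly$ml_axes$proximal_tibial$direction,
                    assembly$ml_axes$intermalleolar$direction,
                    assembly$frames$tibial,
                    c("EXTERNAL", "INTERNAL"))
}

#' Full leg alignment analysis
#'
#' Runs the complete pipeline: joint centres, coordinate systems, the
#' knee-extension prerequisite (per `angles.extension_policy`), joint
#' orientations, and the eight alignment angles. Deterministic given inputs
#' and configuration.
#'
#' @param femur a FEMUR [bone_model()].
#' @param tibfib a TIBIA_FIBULA [bone_model()] of the same side.
#' @param config a [legalign_config()] or named list of keys.
#' @return a `legalign_report`; see [tidy.legalign_report()].
#' @export
analyze_leg <- function(femur, tibfib, config = legalign_config()) {
  config <- as_legalign_config(config)
  stage <- "assembly"
  result <- tryCatch({
    assembly <- build_leg_assembly(femur, tibfib, config)

    stage <- "extension"
    residual0 <- assembly$extension_residual_deg
    if (residual0 > config$angles.extension_threshold_deg) {
      assembly <- switch(config$angles.extension_policy,
        auto = virtual_extend(assembly),
        strict = stop_legalign(
          sprintf("knee not extended: sagittal residual %.3f deg exceeds %.3f deg",
                  residual0, config$angles.extension_threshold_deg),
          "legalign_extension_error", residual = residual0),
        ignore = {
          warning(sprintf(
            "knee not extended (residual %.3f deg); coronal angles computed anyway",
            residual0), call. = FALSE)
          assembly
        })
    }

    stage <- "supracondylar"
    orientations <- joint_orientations(assembly)

    stage <- "angles"
    slopes <- compute_slope_angles(assembly, orientations)
    fva <- compute_fva(assembly, orientations)
    tta <- compute_tta(assembly, orientations)
    angles <- c(HKAA = compute_hkaa(assembly, orientations),
                mLDFA = compute_mldfa(assembly, orientations),
                mMPTA = compute_mmpta(assembly, orientations),
                mPDFA = compute_mpdfa(assembly, orientations),
                mMPPTA = unname(slopes["mMPPTA"]),
                mLPPTA = unname(slopes["mLPPTA"]),
                FVA = fva$angle, TTA = tta$angle)
    fit_res <- c(assembly$fit_residuals,
                 ptj_medial = orientations$PTJ_medial$rms_mm,
                 ptj_lateral = orientations$PTJ_lateral$rms_mm,
                 ptj_combined = orientations$PTJ_combined$rms_mm)
    new_report(angles = angles,
               directions = c(FVA = fva$direction, TTA = tta$direction),
               extension_residual_deg = assembly$extension_residual_deg,
               initial_extension_residual_deg = residual0,
               side = assembly$side,
               fit_residuals = fit_res,
               femur = femur, tibfib = tibfib, config = config,
               assembly = assembly, orientations = orientations)
  }, legalign_error = function(e) {
    stop_legalign(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                  class = class(e)[1], stage = stage, parent = e,
                  residual = e$residual)
  })
  result
}
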