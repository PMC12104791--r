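# Synthetic bone phantoms with analytic ground truth.
#
# A right leg is constructed in the canonical patient frame (x right,
# y anterior, z cranial) and mirrored for left sides:
#
# * femoral head      sphere sector of head_radius centred on the hip point;
# * femoral neck      full cylindrical band about the neck axis, whose axial
#                     direction realizes the femoral version;
# * condyles          two sector bands of a shared cylinder (the truth
#                     medial-lateral axis), embedded in a closed distal shell
#                     (full cylinder + end caps) so the axis-bone
#                     intersections are well defined;
# * trochlea          an anterior sector band of the same shell, disjoint
#                     from the condyles (the sulcus terminalis split);
# * plateaus          planar parallelogram patches tilted by the coronal
#                     deformity and per-compartment posterior slopes;
# * plafond/malleoli  planar patches whose centroid line realizes the tibial
#                     torsion against the plateau-centroid line;
# * shafts            unlabeled coarse tubes (inert downstream).
#
# Knee flexion is a rigid rotation of the tibia/fibula about the condylar
# axis. Gaussian noise (if any) displaces vertices along vertex normals,
# emulating segmentation surface error while keeping labels on-surface.
# Ground truth is derived in closed form from the construction parameters
# BEFORE noise, and truth angles are computed from the analytic primitives of
# the UNFLEXED configuration (the quantities an extended-knee analysis should
# recover).

#' Phantom specification
#'
#' All lengths in millimetres, angles in degrees. Positive `femoral_varus_deg`
#' and `tibial_varus_deg` build a varus leg (HKAA below 180); positive
#' `femoral_version_deg` is anteversion; positive `tibial_torsion_deg` is
#' external torsion; `sfj_pitch_deg` is the anterior-proximal inclination of
#' the supracondylar line (mPDFA = 90 - pitch).
#'
#' @param femur_length_mm,tibia_length_mm bone lengths.
#' @param head_radius_mm,condyle_radius_mm sphere/cylinder radii.
#' @param intercondylar_halfwidth_mm half-distance between condyle band centres.
#' @param plateau_halfwidth_mm half-distance between plateau centroids.
#' @param malleolar_halfwidth_mm half-distance between malleolar centroids.
#' @param femoral_varus_deg,tibial_varus_deg coronal joint-line tilts.
#' @param posterior_slope_medial_deg,posterior_slope_lateral_deg tibial slopes.
#' @param femoral_version_deg,tibial_torsion_deg axial-plane build angles.
#' @param knee_flexion_deg rigid flexion applied to the tibia/fibula.
#' @param sfj_pitch_deg supracondylar-line sagittal pitch.
#' @param side `"RIGHT"` or `"LEFT"`.
#' @param mesh_density_mm target edge length (0.5-5 mm).
#' @param noise_sigma_mm Gaussian surface noise along vertex normals.
#' @param seed RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(femur_length_mm = 420, tibia_length_mm = 380,
                         head_radius_mm = 24, condyle_radius_mm = 22,
                         intercondylar_halfwidth_mm = 24,
                         plateau_halfwidth_mm = 23,
                         malleolar_halfwidth_mm = 28,
                         femoral_varus_deg = 0, tibial_varus_deg = 0,
                         posterior_slope_medial_deg = 0,
                         posterior_slope_lateral_deg = 0,
                         femoral_version_deg = 15, tibial_torsion_deg = 25,
                         knee_flexion_deg = 0, sfj_pitch_deg = 0,
                         side = "RIGHT", mesh_density_mm = 1.5,
                         noise_sigma_mm = 0, seed = 1L) {
  spec <- list(femur_length_mm = femur_length_mm, tibia_length_mm = tibia_length_mm,
               head_radius_mm = head_radius_mm, condyle_radius_mm = condyle_radius_mm,
               intercondylar_halfwidth_mm = intercondylar_halfwidth_mm,
               plateau_halfwidth_mm = plateau_halfwidth_mm,
               malleolar_halfwidth_mm = malleolar_halfwidth_mm,
               femoral_varus_deg = femoral_varus_deg,
               tibial_varus_deg = tibial_varus_deg,
               posterior_slope_medial_deg = posterior_slope_medial_deg,
               posterior_slope_lateral_deg = posterior_slope_lateral_deg,
               femoral_version_deg = femoral_version_deg,
               tibial_torsion_deg = tibial_torsion_deg,
               knee_flexion_deg = knee_flexion_deg,
               sfj_pitch_deg = sfj_pitch_deg,
               side = match.arg(toupper(side), c("RIGHT", "LEFT")),
               mesh_density_mm = mesh_density_mm,
               noise_sigma_mm = noise_sigma_mm, seed = as.integer(seed))
  lengths <- c("femur_length_mm", "tibia_length_mm", "head_radius_mm",
               "condyle_radius_mm", "intercondylar_halfwidth_mm",
               "plateau_halfwidth_mm", "malleolar_halfwidth_mm")
  if (any(unlist(spec[lengths]) <= 0)) {
    stop_legalign("phantom lengths must be positive", "legalign_spec_error")
  }
  defo <- c("femoral_varus_deg", "tibial_varus_deg", "posterior_slope_medial_deg",
            "posterior_slope_lateral_deg", "sfj_pitch_deg")
  if (any(abs(unlist(spec[defo])) > 30 + 1e-9)) {
    stop_legalign("phantom deformity angles must lie within +/-30 degrees",
                  "legalign_spec_error")
  }
  if (abs(spec$knee_flexion_deg) > 45 + 1e-9) {
    stop_legalign("knee flexion must lie within +/-45 degrees", "legalign_spec_error")
  }
  if (spec$mesh_density_mm < 0.5 || spec$mesh_density_mm > 5) {
    stop_legalign("mesh density must lie in [0.5, 5] mm", "legalign_spec_error")
  }
  if (spec$noise_sigma_mm < 0) {
    stop_legalign("noise sigma must be non-negative", "legalign_spec_error")
  }
  structure(spec, class = "phantom_spec")
}

DEG <- pi / 180

# Breakpoints covering [lo, hi] that include every boundary in `bounds`,
# subdivided to at most `step` spacing (arc length units).
seg_breaks <- function(lo, hi, bounds, step) {
  b <- sort(unique(c(lo, hi, bounds[bounds > lo & bounds < hi])))
  out <- numeric(0)
  for (i in seq_len(length(b) - 1)) {
    n <- max(1, ceiling((b[i + 1] - b[i]) / step))
    out <- c(out, seq(b[i], b[i + 1], length.out = n + 1)[-(n + 1)])
  }
  c(out, hi)
}

# --- mesh part builders -----------------------------------------------------
# Each part is list(vertices, faces, cell = data.frame per face) so regions
# can be assigned from parametric cell centres.

part_cylinder <- function(origin, axis, u, v, radius, s_breaks, theta_breaks,
                          closed_theta = TRUE, caps = FALSE) {
  ns <- length(s_breaks)
  th <- if (closed_theta) theta_breaks[-length(theta_breaks)] else theta_breaks
  nt <- length(th)
  ring <- t(vapply(th, function(t) radius * (cos(t) * u + sin(t) * v), numeric(3)))
  verts <- do.call(rbind, lapply(s_breaks, function(s) {
    sweep(ring, 2, origin + s * axis, "+")
  }))
  idx <- function(i, j) (i - 1) * nt + ((j - 1) %% nt) + 1
  nseg <- if (closed_theta) nt else nt - 1
  faces <- matrix(0L, 0, 3)
  fs <- ft <- numeric(0)
  for (i in seq_len(ns - 1)) {
    j <- seq_len(nseg)
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    faces <- rbind(faces, cbind(a, b, cc), cbind(a, cc, d))
    smid <- (s_breaks[i] + s_breaks[i + 1]) / 2
    tmid <- (theta_breaks[j] + theta_breaks[j + 1]) / 2
    fs <- c(fs, rep(smid, 2 * nseg))
    ft <- c(ft, tmid, tmid)  # block of (a,b,cc) rows, then block of (a,cc,d)
  }
  part <- list(vertices = verts, faces = faces,
               cell = data.frame(s = fs, theta = ft))
  if (caps) {
    for (end in c(1, ns)) {
      ctr <- origin + s_breaks[end] * axis
      base <- nrow(part$vertices)
      ringv <- verts[((end - 1) * nt + 1):((end - 1) * nt + nt), , drop = FALSE]
      part$vertices <- rbind(part$vertices, ctr, ringv)
      j <- seq_len(nt)
      rim <- base + 1 + j
      nxt <- base + 1 + (j %% nt) + 1
      tri <- if (end == 1) cbind(base + 1, nxt, rim) else cbind(base + 1, rim, nxt)
      part$faces <- rbind(part$faces, tri)
      part$cell <- rbind(part$cell, data.frame(s = rep(NA_real_, nt),
                                               theta = rep(NA_real_, nt)))
    }
  }
  part
}

part_parallelogram <- function(center, half_u, half_v, n_u, n_v) {
  al <- seq(-1, 1, length.out = n_u + 1)
  be <- seq(-1, 1, length.out = n_v + 1)
  verts <- do.call(rbind, lapply(be, function(b) {
    t(vapply(al, function(a) center + a * half_u + b * half_v, numeric(3)))
  }))
  idx <- function(i, j) (j - 1) * (n_u + 1) + i
  faces <- matrix(0L, 0, 3)
  for (j in seq_len(n_v)) {
    i <- seq_len(n_u)
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    faces <- rbind(faces, cbind(a, b, cc), cbind(a, cc, d))
  }
  list(vertices = verts, faces = faces,
       cell = data.frame(s = rep(NA_real_, nrow(faces)),
                         theta = rep(NA_real_, nrow(faces))))
}

part_sphere_cap <- function(center, radius, pole_dir, half_angle, step) {
  B <- complete_basis(pole_dir)
  q1 <- B[, 1]; q2 <- B[, 2]; p <- B[, 3]
  npsi <- max(3, ceiling(radius * half_angle / step))
  psis <- seq(0, half_angle, length.out = npsi + 1)[-1]
  nphi <- max(8, ceiling(2 * pi * radius / step))
  phis <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  verts <- center + radius * p
  for (ps in psis) {
    ringdir <- t(vapply(phis, function(ph) {
      cos(ps) * p + sin(ps) * (cos(ph) * q1 + sin(ph) * q2)
    }, numeric(3)))
    verts <- rbind(verts, sweep(ringdir * radius, 2, center, "+"))
  }
  faces <- matrix(0L, 0, 3)
  ring_start <- function(k) 1 + (k - 1) * nphi + 1
  j <- seq_len(nphi)
  jn <- (j %% nphi) + 1
  faces <- rbind(faces, cbind(1L, ring_start(1) - 1 + j, ring_start(1) - 1 + jn))
  if (length(psis) > 1) {
    for (k in seq_len(length(psis) - 1)) {
      a <- ring_start(k) - 1 + j; b <- ring_start(k + 1) - 1 + j
      cc <- ring_start(k + 1) - 1 + jn; d <- ring_start(k) - 1 + jn
      faces <- rbind(faces, cbind(a, b, cc), cbind(a, cc, d))
    }
  }
  list(vertices = verts, faces = faces,
       cell = data.frame(s = rep(NA_real_, nrow(faces)),
                         theta = rep(NA_real_, nrow(faces))))
}

# Combine parts into a mesh plus face-region map. `region_of[[k]]` is either
# NA or a function(cell)->logical vector, or a region name for all faces.
combine_parts <- function(parts, regions_of) {
  vofs <- 0L; fofs <- 0L
  verts <- list(); faces <- list()
  regions <- list()
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    verts[[k]] <- p$vertices
    faces[[k]] <- p$faces + vofs
    reg <- regions_of[[k]]
    if (!is.null(reg) && !identical(reg, NA)) {
      if (is.character(reg)) {
        regions[[reg]] <- c(regions[[reg]], fofs + seq_len(nrow(p$faces)))
      } else {
        for (nm in names(reg)) {
          sel <- reg[[nm]](p$cell)
          regions[[nm]] <- c(regions[[nm]], fofs + which(sel))
        }
      }
    }
    vofs <- vofs + nrow(p$vertices)
    fofs <- fofs + nrow(p$faces)
  }
  list(mesh = leg_mesh(do.call(rbind, verts), do.call(rbind, faces),
                       validate = FALSE),
       regions = regions)
}

# Analytic extremum of dot(P(s, theta), dir) over a cylinder-band patch
# P(s,t) = q0 + s*axis + r(cos t * u + sin t * v), s in [s0,s1], t in [t0,t1].
# Ties (coefficient ~ 0) resolve to the interval midpoint, matching the
# vertex-tie averaging of the extremal-point searches.
cyl_patch_extremum <- function(dir, q0, axis, u, v, r, s_range, t_range,
                               maximize = TRUE, tie_eps = 1e-12) {
  sgn <- if (maximize) 1 else -1
  ca <- sgn * sum(dir * axis)
  s_star <- if (abs(ca) < tie_eps) mean(s_range) else if (ca > 0) s_range[2] else s_range[1]
  A <- sgn * r * sum(dir * u)
  B <- sgn * r * sum(dir * v)
  f <- function(t) A * cos(t) + B * sin(t)
  t0 <- atan2(B, A)
  cands <- c(t_range[1], t_range[2])
  for (shift in c(-2 * pi, 0, 2 * pi)) {
    tc <- t0 + shift
    if (tc >= t_range[1] && tc <= t_range[2]) cands <- c(cands, tc)
  }
  vals <- f(cands)
  best <- max(vals)
  sel <- cands[vals >= best - tie_eps]
  t_star <- mean(sel)
  as.numeric(q0 + s_star * axis + r * (cos(t_star) * u + sin(t_star) * v))
}

# --- the generator ----------------------------------------------------------

#' Generate a labeled phantom leg with analytic ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `femur` and `tibfib` ([bone_model()]s that pass all
#'   validation) and `truth` (class `phantom_truth`): construction points and
#'   axes in the emission frame, the eight ground-truth angles with direction
#'   labels, and the expected extension residual. Truth is independent of
#'   mesh density and noise.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gf <- spec$femoral_varus_deg * DEG
  gt <- spec$tibial_varus_deg * DEG
  sm <- spec$posterior_slope_medial_deg * DEG
  sl <- spec$posterior_slope_lateral_deg * DEG
  nu <- spec$femoral_version_deg * DEG
  tau <- spec$tibial_torsion_deg * DEG
  phi <- spec$knee_flexion_deg * DEG
  pitch <- spec$sfj_pitch_deg * DEG
  Lf <- spec$femur_length_mm; Lt <- spec$tibia_length_mm
  Rh <- spec$head_radius_mm; Rc <- spec$condyle_radius_mm
  w <- spec$intercondylar_halfwidth_mm
  wp <- spec$plateau_halfwidth_mm; mw <- spec$malleolar_halfwidth_mm
  h <- spec$mesh_density_mm

  # ---- femur (world frame; right side) ----
  K <- c(0, 0, 0)
  H <- c(0, 0, Lf)
  Rf <- rotation_about_axis(c(0, 1, 0), gf)
  a_dir <- as.numeric(Rf %*% c(1, 0, 0))      # condylar axis, medial -> lateral
  e_d <- as.numeric(Rf %*% c(0, 0, -1))       # block distal
  e_p <- c(0, -1, 0)                           # posterior (unchanged by Rot_y)

  band <- 8                                    # condyle band half-width (mm)
  wt <- 10                                     # trochlea band half-width (mm)
  Xc <- w + band + 4                           # shell half-length
  th_condyle <- c(-45, 120) * DEG
  th_troch_hi <- -55 * DEG
  # trochlear proximal border solving the requested supracondylar pitch:
  # plane through condyle-edge points (y_p, z_p) and trochlea-edge (y_t, z_t)
  # satisfies (z_t - z_p) = tan(pitch) (y_t - y_p) in the block frame.
  y_p <- -Rc * sin(th_condyle[2]); z_p <- -Rc * cos(th_condyle[2])
  g <- function(th) (-Rc * cos(th) - z_p) - tan(pitch) * (-Rc * sin(th) - y_p)
  th_troch_lo <- uniroot(g, interval = c(-170 * DEG, th_troch_hi - 1e-6),
                         tol = 1e-14)$root

  th_breaks <- seg_breaks(-pi, pi,
                          c(th_troch_lo, th_troch_hi, th_condyle), h / Rc)
  x_bounds <- c(-w - band, -w + band, -wt, wt, w - band, w + band)
  x_breaks <- seg_breaks(-Xc, Xc, x_bounds, h)
  shell <- part_cylinder(K, a_dir, e_d, e_p, Rc, x_breaks, th_breaks,
                         closed_theta = TRUE, caps = TRUE)
  in_box <- function(slo, shi, tlo, thi) {
    force(slo); force(shi); force(tlo); force(thi)
    function(cell) {
      !is.na(cell$s) & cell$s > slo & cell$s < shi &
        cell$theta > tlo & cell$theta < thi
    }
  }
  shell_regions <- list(
    MEDIAL_FEMORAL_CONDYLE = in_box(-w - band, -w + band, th_condyle[1], th_condyle[2]),
    LATERAL_FEMORAL_CONDYLE = in_box(w - band, w + band, th_condyle[1], th_condyle[2]),
    TROCHLEA = in_box(-wt, wt, th_troch_lo, th_troch_hi)
  )

  # neck: version nu about the shaft axis, depression delta below axial plane
  delta <- 30 * DEG
  n_dir <- c(cos(delta) * cos(nu), -cos(delta) * sin(nu), -sin(delta))
  Bn <- complete_basis(n_dir)
  rn <- 15
  neck <- part_cylinder(H, n_dir, Bn[, 1], Bn[, 2], rn,
                        seg_breaks(26, 40, numeric(0), h),
                        seg_breaks(-pi, pi, numeric(0), h / rn))
  neck_center <- H + mean(c(26, 40)) * n_dir

  head <- part_sphere_cap(H, Rh, -n_dir, 115 * DEG, h)

  coarse <- max(h, 6)
  shaft_f <- part_cylinder(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), 13,
                           seg_breaks(30, Lf - 28, numeric(0), coarse),
                           seg_breaks(-pi, pi, numeric(0), coarse / 13))

  femur_built <- combine_parts(
    list(shell, neck, head, shaft_f),
    list(shell_regions, "FEMORAL_NECK", "FEMORAL_HEAD", NA))

  # ---- tibia/fibula (local frame: proximal tibial centre at origin) ----
  p_hat <- c(cos(gt), 0, -sin(gt))             # plateau ML axis, medial -> lateral
  v_slope <- function(s) c(0, cos(s), sin(s))  # AP in-plane axis, slope s
  n_u <- max(2, ceiling(22 / h)); n_v <- max(2, ceiling(28 / h))
  plat_m <- part_parallelogram(-wp * p_hat, 11 * p_hat, 14 * v_slope(sm), n_u, n_v)
  plat_l <- part_parallelogram(+wp * p_hat, 11 * p_hat, 14 * v_slope(sl), n_u, n_v)

  A_loc <- c(0, 0, -Lt)
  d_hat <- c(cos(tau), -sin(tau), 0)           # intermalleolar, medial -> lateral
  d_perp <- c(sin(tau), cos(tau), 0)
  plafond <- part_parallelogram(A_loc, 14 * c(1, 0, 0), 12 * c(0, 1, 0),
                                max(2, ceiling(28 / h)), max(2, ceiling(24 / h)))
  mall_m <- part_parallelogram(A_loc - mw * d_hat, 8 * c(0, 0, 1), 7 * d_perp,
                               max(2, ceiling(16 / h)), max(2, ceiling(14 / h)))
  mall_l <- part_parallelogram(A_loc + mw * d_hat, 8 * c(0, 0, 1), 7 * d_perp,
                               max(2, ceiling(16 / h)), max(2, ceiling(14 / h)))
  shaft_t <- part_cylinder(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), 12,
                           seg_breaks(-Lt + 25, -12, numeric(0), coarse),
                           seg_breaks(-pi, pi, numeric(0), coarse / 12))
  tib_built <- combine_parts(
    list(plat_m, plat_l, plafond, mall_m, mall_l, shaft_t),
    list("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU", "TIBIAL_PLAFOND",
         "MEDIAL_MALLEOLUS_FACET", "LATERAL_MALLEOLUS_FACET", NA))

  # ---- assemble tibia in world ----
  chi <- gf + gt                                # total coronal deformity
  R1 <- rotation_about_axis(c(0, 1, 0), chi)
  dk <- Rc + 4                                  # knee gap below the condyles
  t1 <- K + as.numeric(R1 %*% c(0, 0, -dk))
  tf_coronal <- rigid_transform(R1, t1)
  tf_flex <- rigid_rotation_about_line(K, a_dir, -phi)
  tf_tib <- rigid_compose(tf_flex, tf_coronal)
  tib_built$mesh <- transform_mesh(tib_built$mesh, tf_tib)

  # ---- analytic truth (pre-noise) ----
  truth <- phantom_truth(spec, list(
    K = K, H = H, a_dir = a_dir, e_d = e_d, e_p = e_p, Rc = Rc, w = w,
    band = band, wt = wt, Xc = Xc, th_condyle = th_condyle,
    th_troch = c(th_troch_lo, th_troch_hi), n_dir = n_dir,
    neck_center = neck_center, p_hat = p_hat, wp = wp, mw = mw,
    d_hat = d_hat, A_loc = A_loc, sm = sm, sl = sl,
    tf_coronal = tf_coronal, tf_tib = tf_tib, dk = dk, Lt = Lt))

  # ---- mirror for left side ----
  femur_mesh <- femur_built$mesh
  tib_mesh <- tib_built$mesh
  if (spec$side == "LEFT") {
    mirror_mesh <- function(m) {
      v <- m$vertices; v[, 1] <- -v[, 1]
      leg_mesh(v, m$faces[, c(1, 3, 2), drop = FALSE], validate = FALSE)
    }
    femur_mesh <- mirror_mesh(femur_mesh)
    tib_mesh <- mirror_mesh(tib_mesh)
  }

  # ---- noise ----
  if (spec$noise_sigma_mm > 0) {
    set.seed(spec$seed)
    for (nm in c("femur", "tib")) {
      m <- if (nm == "femur") femur_mesh else tib_mesh
      vn <- vertex_normals(m)
      disp <- rnorm(nrow(m$vertices), sd = spec$noise_sigma_mm)
      m$vertices <- m$vertices + vn * disp
      if (nm == "femur") femur_mesh <- m else tib_mesh <- m
    }
  }

  femur <- bone_model("FEMUR", spec$side, femur_mesh, femur_built$regions)
  tibfib <- bone_model("TIBIA_FIBULA", spec$side, tib_mesh, tib_built$regions)
  list(femur = femur, tibfib = tibfib, truth = truth)
}

# Mirror truth primitives through x = 0.
mirror_point <- function(p) c(-p[1], p[2], p[3])
mirror_line <- function(l) line3(mirror_point(l$point), mirror_point(l$direction))
mirror_plane <- function(pl) plane3(mirror_point(pl$point), mirror_point(pl$normal))

# Assemble the analytic ground truth. Geometry arrives in right-side world
# coordinates; angles are computed from the UNFLEXED configuration, then
# everything is mirrored if the spec is a left side (angles are side
# invariant by construction).
phantom_truth <- function(spec, geo) {
  tib_primitives <- function(tf) {
    list(
      knee_tibial = rigid_apply_points(tf, c(0, 0, 0)),
      ankle = rigid_apply_points(tf, geo$A_loc),
      plateau_ml = rigid_apply_line(tf, line3(c(0, 0, 0), geo$p_hat)),
      intermalleolar = rigid_apply_line(tf, line3(geo$A_loc, geo$d_hat)),
      ptj_medial = rigid_apply_plane(tf, plane3(-geo$wp * geo$p_hat,
        cross3(geo$p_hat, c(0, cos(geo$sm), sin(geo$sm))))),
      ptj_lateral = rigid_apply_plane(tf, plane3(geo$wp * geo$p_hat,
        cross3(geo$p_hat, c(0, cos(geo$sl), sin(geo$sl))))),
      ptj_combined = rigid_apply_plane(tf, plateau_tls_plane(geo))
    )
  }
  # supracondylar truth points: continuous argmax of z (the truth femoral
  # frame's proximal direction) over each patch
  zhat <- c(0, 0, 1)
  sfj_points <- rbind(
    cyl_patch_extremum(zhat, geo$K, geo$a_dir, geo$e_d, geo$e_p, geo$Rc,
                       c(-geo$wt, geo$wt), geo$th_troch),
    cyl_patch_extremum(zhat, geo$K, geo$a_dir, geo$e_d, geo$e_p, geo$Rc,
                       c(-geo$w - geo$band, -geo$w + geo$band), geo$th_condyle),
    cyl_patch_extremum(zhat, geo$K, geo$a_dir, geo$e_d, geo$e_p, geo$Rc,
                       c(geo$w - geo$band, geo$w + geo$band), geo$th_condyle))
  nsfj <- cross3(sfj_points[2, ] - sfj_points[1, ], sfj_points[3, ] - sfj_points[1, ])
  sfj_plane <- plane3(colMeans(sfj_points),
                      if (sum(nsfj * zhat) < 0) -unitize(nsfj) else unitize(nsfj))

  tp0 <- tib_primitives(geo$tf_coronal)   # unflexed
  tp1 <- tib_primitives(geo$tf_tib)       # as emitted (possibly flexed)

  prim0 <- list(
    hip = geo$H, knee_femoral = geo$K,
    knee_tibial = tp0$knee_tibial, ankle = tp0$ankle,
    neck_center = geo$neck_center,
    condylar_axis = line3(geo$K, geo$a_dir),
    neck_femur = line3(geo$H, geo$n_dir),
    plateau_ml = tp0$plateau_ml, intermalleolar = tp0$intermalleolar,
    ptj_medial = tp0$ptj_medial, ptj_lateral = tp0$ptj_lateral,
    ptj_combined = tp0$ptj_combined,
    sfj = sfj_plane, sfj_points = sfj_points, dfj_direction = geo$a_dir)

  angles <- phantom_truth_angles(prim0, side = "RIGHT")

  prim1 <- prim0
  prim1$knee_tibial <- tp1$knee_tibial
  prim1$ankle <- tp1$ankle
  prim1$plateau_ml <- tp1$plateau_ml
  prim1$intermalleolar <- tp1$intermalleolar
  prim1$ptj_medial <- tp1$ptj_medial
  prim1$ptj_lateral <- tp1$ptj_lateral
  prim1$ptj_combined <- tp1$ptj_combined
  residual <- truth_extension_residual(prim1)

  if (spec$side == "LEFT") {
    for (nm in c("hip", "knee_femoral", "knee_tibial", "ankle", "neck_center")) {
      prim1[[nm]] <- mirror_point(prim1[[nm]])
    }
    for (nm in c("condylar_axis", "neck_femur", "plateau_ml", "intermalleolar")) {
      prim1[[nm]] <- mirror_line(prim1[[nm]])
    }
    for (nm in c("ptj_medial", "ptj_lateral", "ptj_combined", "sfj")) {
      prim1[[nm]] <- mirror_plane(prim1[[nm]])
    }
    prim1$sfj_points <- t(apply(prim1$sfj_points, 1, mirror_point))
    prim1$dfj_direction <- mirror_point(prim1$dfj_direction)
  }

  structure(list(
    spec = spec,
    angles_deg = angles$angles,
    directions = angles$directions,
    extension_residual_deg = residual,
    primitives = prim1
  ), class = "phantom_truth")
}

# Analytic total-least-squares plane over the two plateau parallelograms
# (closed-form surface second moments; no mesh involved).
plateau_tls_plane <- function(geo) {
  mk <- function(center, U1, U2) {
    area <- 2 * 2 * vnorm(cross3(U1, U2))  # |(2U1) x (2U2)| / 2 * 2 -> 4|U1xU2|
    cov <- (tcrossprod(U1) + tcrossprod(U2)) / 3
    list(c = center, A = area, cov = cov)
  }
  pm <- mk(-geo$wp * geo$p_hat, 11 * geo$p_hat, 14 * c(0, cos(geo$sm), sin(geo$sm)))
  pl <- mk(+geo$wp * geo$p_hat, 11 * geo$p_hat, 14 * c(0, cos(geo$sl), sin(geo$sl)))
  Atot <- pm$A + pl$A
  cbar <- (pm$A * pm$c + pl$A * pl$c) / Atot
  M <- pm$A * (pm$cov + tcrossprod(pm$c - cbar)) +
       pl$A * (pl$cov + tcrossprod(pl$c - cbar))
  n <- eigen(M, symmetric = TRUE)$vectors[, 3]
  if (n[3] < 0) n <- -n
  plane3(cbar, n)
}

# Truth extension residual: angle between mFA and mTA projected on the truth
# leg sagittal plane.
truth_extension_residual <- function(prim) {
  zleg <- unitize(prim$hip - prim$ankle)
  xleg <- unitize(prim$condylar_axis$direction -
                    sum(prim$condylar_axis$direction * zleg) * zleg)
  f <- project_direction_onto_plane(unitize(prim$hip - prim$knee_femoral), xleg)
  t <- project_direction_onto_plane(unitize(prim$knee_tibial - prim$ankle), xleg)
  angle_between(f, t)
}

#' Recompute ground-truth angles from truth axes and planes
#'
#' Applies the documented angle conventions to the analytic construction
#' primitives (no meshes involved); used for the truth self-consistency
#' contract.
#'
#' @param prim truth primitive list (see [generate_phantom()] `$primitives`).
#' @param side `"RIGHT"` or `"LEFT"`.
#' @return list with `angles` (named vector, degrees) and `directions`.
#' @export
phantom_truth_angles <- function(prim, side = "RIGHT") {
  hint <- diag(3)
  fem_frame <- build_frame(prim$knee_femoral, prim$hip - prim$knee_femoral,
                           prim$condylar_axis$direction, hint)
  tib_frame <- build_frame(prim$knee_tibial, prim$knee_tibial - prim$ankle,
                           prim$plateau_ml$direction, hint)
  leg_frame <- build_frame(prim$knee_femoral, prim$hip - prim$ankle,
                           prim$condylar_axis$direction, hint)
  mfa <- unitize(prim$hip - prim$knee_femoral)
  mta <- unitize(prim$knee_tibial - prim$ankle)

  f <- project_direction_onto_plane(mfa, leg_frame$y)
  t <- project_direction_onto_plane(-mta, leg_frame$y)
  alpha <- angle_between(f, t)
  med <- sum((f + t) * frame_medial(leg_frame, side))
  hkaa <- if (med > 1e-12) alpha else 360 - alpha

  dfj <- orient_towards(prim$dfj_direction, frame_lateral(leg_frame, side))
  mldfa <- angle_between(project_direction_onto_plane(mfa, leg_frame$y),
                         project_direction_onto_plane(dfj, leg_frame$y))

  coronal <- plane3(leg_frame$origin, leg_frame$y)
  jl <- orient_towards(plane_plane_intersection_dir(prim$ptj_combined, coronal),
                       frame_medial(leg_frame, side))
  mmpta <- angle_between(project_direction_onto_plane(mta, leg_frame$y), jl)

  mpdfa <- sagittal_posterior_angle(mfa, prim$sfj, fem_frame)
  mmppta <- sagittal_posterior_angle(mta, prim$ptj_medial, tib_frame)
  mlppta <- sagittal_posterior_angle(mta, prim$ptj_lateral, tib_frame)

  ml_sign <- if (side == "RIGHT") 1 else -1
  nfa_ml <- prim$neck_femur$direction
  cond_ml <- orient_towards(prim$condylar_axis$direction, ml_sign * hint[1, ])
  fva <- axial_acute_angle(cond_ml, nfa_ml, fem_frame,
                           c("ANTEVERSION", "RETROVERSION"))
  plat_ml <- orient_towards(prim$plateau_ml$direction, ml_sign * hint[1, ])
  ima_ml <- orient_towards(prim$intermalleolar$direction, ml_sign * hint[1, ])
  tta <- axial_acute_angle(plat_ml, ima_ml, tib_frame, c("EXTERNAL", "INTERNAL"))

  list(angles = c(HKAA = hkaa, mLDFA = mldfa, mMPTA = mmpta, mPDFA = mpdfa,
                  mMPPTA = mmppta, mLPPTA = mlppta,
                  FVA = fva$angle, TTA = tta$angle),
       directions = c(FVA = fva$direction, TTA = tta$direction))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> side %s, extension residual %.2f deg\n",
              x$spec$side, x$extension_residual_deg))
  print(round(x$angles_deg, 3))
  invisible(x)
}

# --- presets ----------------------------------------------------------------

#' Phantom preset suites
#'
#' Fixture specifications used by the validation suite, with the tolerance
#' each preset is expected to meet (degrees, against analytic truth).
#'
#' @param preset one of `"NEUTRAL"`, `"VARUS5"`, `"VALGUS8"`, `"FLEXED10"`,
#'   `"TORSION_SWEEP"`, `"NOISY"`.
#' @return tibble with columns `preset`, `case`, `spec` (list column of
#'   [phantom_spec()]s) and `tol_deg`.
#' @export
phantom_suite <- function(preset = c("NEUTRAL", "VARUS5", "VALGUS8", "FLEXED10",
                                     "TORSION_SWEEP", "NOISY")) {
  preset <- match.arg(preset)
  mk <- function(case, tol, ...) {
    tibble::tibble(preset = preset, case = case,
                   spec = list(phantom_spec(...)), tol_deg = tol)
  }
  switch(preset,
    NEUTRAL = mk("neutral", 0.2),
    VARUS5 = mk("varus5", 0.2, femoral_varus_deg = 2, tibial_varus_deg = 3),
    VALGUS8 = mk("valgus8", 0.2, femoral_varus_deg = -5, tibial_varus_deg = -3),
    FLEXED10 = mk("flexed10", 0.5, knee_flexion_deg = 10),
    TORSION_SWEEP = dplyr::bind_rows(lapply(c(-20, -10, 0, 10, 20, 30), function(tq) {
      mk(sprintf("torsion%+d", tq), 0.2, tibial_torsion_deg = tq)
    })),
    NOISY = dplyr::bind_rows(lapply(1:10, function(s) {
      mk(sprintf("noisy_seed%02d", s), 1.0, noise_sigma_mm = 0.2, seed = s)
    }))
  )
}

#' Write a phantom to disk (meshes, labels, truth)
#'
#' Emits `femur.stl`, `tibfib.stl`, `femur_labels.json`, `tibfib_labels.json`
#' and `truth.json` into `out_dir`.
#'
#' @param phantom a [generate_phantom()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bone_model(phantom$femur, file.path(out_dir, "femur.stl"),
                   file.path(out_dir, "femur_labels.json"))
  write_bone_model(phantom$tibfib, file.path(out_dir, "tibfib.stl"),
                   file.path(out_dir, "tibfib_labels.json"))
  tr <- phantom$truth
  jsonlite::write_json(list(
    spec = unclass(tr$spec),
    angles_deg = as.list(tr$angles_deg),
    directions = as.list(tr$directions),
    extension_residual_deg = tr$extension_residual_deg
  ), file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
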