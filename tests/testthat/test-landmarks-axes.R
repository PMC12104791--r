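# Joint centres and central medial-lateral axes.

test_that("hip centre recovers the construction sphere exactly and equivariantly", {
  ph <- neutral_phantom()
  truth <- ph$truth$primitives

  # mesh vertices lie exactly on the construction sphere: exact recovery
  vfit <- fit_sphere(region_points(ph$femur, "FEMORAL_HEAD", "VERTICES"))
  expect_lt(max(abs(vfit$center - truth$hip)), 1e-6)
  expect_lt(abs(vfit$radius - ph$truth$spec$head_radius_mm), 1e-6)
  expect_lt(vfit$rms_mm, 1e-9)

  # area-weighted face centroids sit slightly inside the surface, so the
  # default path carries only a small tessellation bias
  h <- hip_center(ph$femur)
  expect_lt(max(abs(as.numeric(h) - truth$hip)), 0.05)

  set.seed(5)
  tf <- random_rigid()
  fem2 <- legalign:::transform_bone_model(ph$femur, legalign:::rigid_transform(tf$R, tf$t))
  h2 <- hip_center(fem2)
  expect_lt(max(abs(as.numeric(h2) - apply_rigid(tf, as.numeric(h)))), 1e-6)
})

test_that("hip centre stays within 0.2 mm of truth under 0.2 mm surface noise", {
  ph <- cached_phantom("noisy_lm", phantom_spec(noise_sigma_mm = 0.2, seed = 9,
                                                mesh_density_mm = 2))
  h <- hip_center(ph$femur)
  expect_lt(sqrt(sum((as.numeric(h) - ph$truth$primitives$hip)^2)), 0.2)
})

test_that("distal femoral centre is the midpoint of the extreme axis-bone hits", {
  ph <- neutral_phantom()
  k <- distal_femoral_center(ph$femur)
  truth <- ph$truth$primitives
  # symmetric phantom: on the sagittal symmetry plane and at the construction centre
  expect_lt(abs(as.numeric(k)[1]), 1e-6)
  expect_lt(max(abs(as.numeric(k) - truth$knee_femoral)), 1e-6)
  # midpoint lies on the fitted axis
  fit <- attr(k, "fit")
  rel <- as.numeric(k) - fit$axis$point
  off <- rel - sum(rel * fit$axis$direction) * fit$axis$direction
  expect_lt(sqrt(sum(off^2)), 1e-9)
  # condyle-region scope has no cap faces to hit
  expect_error(distal_femoral_center(ph$femur, scope = "condyle_regions"),
               class = "legalign_construction_error")
})

test_that("asymmetric shells move the centre to the analytic chord midpoint", {
  # condyle bands on a shell whose caps sit at -30 / +40 along the axis:
  # the centre must land at the midpoint +5, not at the fit centroid
  K <- c(0, 0, 0)
  shell <- legalign:::part_cylinder(K, c(1, 0, 0), c(0, 0, -1), c(0, -1, 0), 22,
                                    legalign:::seg_breaks(-30, 40, c(-26, -10, 10, 26), 2),
                                    legalign:::seg_breaks(-pi, pi, c(-45, 120) * pi / 180, 0.1),
                                    caps = TRUE)
  sel <- function(cell, lo, hi) {
    !is.na(cell$s) & cell$s > lo & cell$s < hi &
      cell$theta > -45 * pi / 180 & cell$theta < 120 * pi / 180
  }
  mesh <- leg_mesh(shell$vertices, shell$faces)
  model <- bone_model("FEMUR", "RIGHT", mesh,
                      list(MEDIAL_FEMORAL_CONDYLE = which(sel(shell$cell, -26, -10)),
                           LATERAL_FEMORAL_CONDYLE = which(sel(shell$cell, 10, 26))),
                      require_regions = FALSE)
  k <- distal_femoral_center(model)
  expect_lt(max(abs(as.numeric(k) - c(5, 0, 0))), 1e-6)
})

test_that("proximal tibial centre is the midpoint of the two plateau centroids", {
  ph <- neutral_phantom()
  p <- proximal_tibial_center(ph$tibfib)
  expect_lt(max(abs(p - ph$truth$primitives$knee_tibial)), 1e-6)

  # label permutation leaves the midpoint unchanged
  swapped <- ph$tibfib
  swapped$regions[c("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU")] <-
    swapped$regions[c("LATERAL_TIBIAL_PLATEAU", "MEDIAL_TIBIAL_PLATEAU")]
  expect_equal(proximal_tibial_center(swapped), p, tolerance = 1e-12)

  # unequal-area plateaus: midpoint-of-centroids, NOT the pooled centroid
  tb <- hand_tibfib(
    medial_plateau = rect_part(c(-20, 0, 0), c(16, 0, 0), c(0, 12, 0)),  # larger
    lateral_plateau = rect_part(c(20, 0, 0), c(8, 0, 0), c(0, 6, 0)))    # smaller
  got <- proximal_tibial_center(tb)
  expect_equal(got, c(0, 0, 0), tolerance = 1e-12)          # midpoint of centroids
  am <- 2 * 32 * 12; al <- 2 * 16 * 6
  pooled <- (am * c(-20, 0, 0) + al * c(20, 0, 0)) / (am + al)
  expect_gt(sqrt(sum((got - pooled)^2)), 5)                 # definitions differ here
})

test_that("ankle centre is the pooled area-weighted centroid of three regions", {
  # plafond 60% of the area, malleoli 20% each, at distinct heights
  tb <- hand_tibfib(
    plafond = rect_part(c(0, 0, -300), c(15, 0, 0), c(0, 10, 0)),   # area 600
    mall_m = rect_part(c(-25, 0, -310), c(0, 0, 10), c(0, 5, 0)),   # area 200
    mall_l = rect_part(c(25, 0, -306), c(0, 0, 10), c(0, 5, 0)))    # area 200
  got <- distal_tibfib_center(tb)
  oracle <- (600 * c(0, 0, -300) + 200 * c(-25, 0, -310) + 200 * c(25, 0, -306)) / 1000
  expect_equal(got, oracle, tolerance = 1e-12)

  # pooled-centroid weighting makes the result tessellation invariant
  ph15 <- cached_phantom("neutral1.5", phantom_spec(mesh_density_mm = 1.5))
  ph3 <- neutral_phantom()
  expect_lt(max(abs(distal_tibfib_center(ph15$tibfib) -
                    distal_tibfib_center(ph3$tibfib))), 0.05)
})

test_that("re-meshing at higher density moves every centre by < 0.05 mm", {
  ph15 <- cached_phantom("neutral1.5", phantom_spec(mesh_density_mm = 1.5))
  ph3 <- neutral_phantom()
  pairs <- list(
    c(hip_center(ph15$femur), hip_center(ph3$femur)),
    c(distal_femoral_center(ph15$femur), distal_femoral_center(ph3$femur)),
    c(proximal_tibial_center(ph15$tibfib), proximal_tibial_center(ph3$tibfib)),
    c(distal_tibfib_center(ph15$tibfib), distal_tibfib_center(ph3$tibfib)))
  for (pr in pairs) {
    expect_lt(max(abs(pr[1:3] - pr[4:6])), 0.05)
  }
})

test_that("neck-femur axis matches the construction and guards degeneracy", {
  ph <- cached_phantom("version15", phantom_spec(mesh_density_mm = 2))
  nfa <- neck_femur_axis(ph$femur)
  expect_lt(line_angle_deg(nfa$direction,
                           ph$truth$primitives$neck_femur$direction) * pi / 180,
            1e-3)
  expect_lt(max(abs(nfa$point - ph$truth$primitives$hip)), 0.05)

  # head centre on the neck centroid: degenerate
  bad <- ph$femur
  ctr <- surface_centroid(bad, "FEMORAL_NECK")
  shift <- ctr - as.numeric(hip_center(bad))
  bad$mesh$vertices[legalign:::region_vertex_indices(bad, "FEMORAL_HEAD"), ] <-
    sweep(bad$mesh$vertices[legalign:::region_vertex_indices(bad, "FEMORAL_HEAD"), ],
          2, -shift)
  expect_error(neck_femur_axis(bad), class = "legalign_degeneracy_error")
})

test_that("central ML axes are stored medial-to-lateral and recover torsion", {
  ph <- neutral_phantom()
  right_hint <- c(1, 0, 0)
  dml <- central_ml_axis_distal_femur(ph$femur, right_hint)
  expect_gt(sum(dml$direction * right_hint), 0)  # right leg: m->l points right
  ptl <- central_ml_axis_proximal_tibia(ph$tibfib, right_hint)
  expect_gt(sum(ptl$direction * right_hint), 0)

  # label swap must flip the stored orientation back to canonical
  swapped <- ph$tibfib
  swapped$regions[c("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU")] <-
    swapped$regions[c("LATERAL_TIBIAL_PLATEAU", "MEDIAL_TIBIAL_PLATEAU")]
  ptl2 <- central_ml_axis_proximal_tibia(swapped, right_hint)
  expect_equal(ptl2$direction, ptl$direction, tolerance = 1e-12)

  # torsioned phantom: intermalleolar axis rotated by the construction angle
  pht <- cached_phantom("torsion10", phantom_spec(tibial_torsion_deg = 10,
                                                  mesh_density_mm = 2))
  ima <- intermalleolar_axis(pht$tibfib, right_hint)
  plat <- central_ml_axis_proximal_tibia(pht$tibfib, right_hint)
  expect_equal(line_angle_deg(ima$direction, plat$direction), 10, tolerance = 1e-3)

  # left leg: m->l points patient-left
  phl <- cached_phantom("left3", phantom_spec(side = "LEFT", mesh_density_mm = 3))
  dml_l <- central_ml_axis_distal_femur(phl$femur, right_hint)
  expect_lt(sum(dml_l$direction * right_hint), 0)
})
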