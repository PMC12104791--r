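# Joint orientations and the eight clinical angles.

test_that("condylar tangent line follows the most distal points", {
  ph <- neutral_phantom()
  asm <- build_leg_assembly(ph$femur, ph$tibfib)
  dfj <- condylar_tangent_line(ph$femur, asm$frames$leg)
  # symmetric phantom: the tangent is parallel to the condylar axis and sits
  # one condyle radius below it
  expect_lt(line_angle_deg(dfj$direction, ph$truth$primitives$dfj_direction), 0.05)
  pts <- attr(dfj, "points")
  expect_equal(unname(pts[, 3]), rep(-ph$truth$spec$condyle_radius_mm, 2),
               tolerance = 1e-3)
  # endpoints stay on the labeled condyle bands (the exact x within the band
  # is tie-dependent: every point of the lowest generator is equally distal)
  w <- ph$truth$spec$intercondylar_halfwidth_mm
  expect_true(all(abs(abs(pts[, 1]) - w) <= 8 + 1e-6))

  # hypoplasia model: two flat patches, lateral 3 mm more distal
  d <- 46
  fem <- local({
    pm <- rect_part(c(-d / 2, 0, 0), c(6, 0, 0), c(0, 8, 0))
    pl <- rect_part(c(d / 2, 0, -3), c(6, 0, 0), c(0, 8, 0))
    tro <- rect_part(c(0, 20, 10), c(5, 0, 0), c(0, 0, 5))
    verts <- rbind(pm$vertices, pl$vertices, tro$vertices)
    faces <- rbind(pm$faces, pl$faces + 4, tro$faces + 8)
    bone_model("FEMUR", "RIGHT", leg_mesh(verts, faces),
               list(MEDIAL_FEMORAL_CONDYLE = 1:2, LATERAL_FEMORAL_CONDYLE = 3:4,
                    TROCHLEA = 5:6), require_regions = FALSE)
  })
  frame <- leg_frame_new(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  dfj2 <- condylar_tangent_line(fem, frame)
  expect_equal(line_angle_deg(dfj2$direction, c(1, 0, 0)),
               atan(3 / d) * 180 / pi, tolerance = 0.1 / 3.7)

  # flat patches tie across each whole region; tie-averaging centres the points
  expect_equal(unname(attr(dfj2, "points")["medial", 1:2]), c(-d / 2, 0),
               tolerance = 1e-9)
})

test_that("supracondylar plane matches the three-point construction", {
  ph <- neutral_phantom()
  asm <- build_leg_assembly(ph$femur, ph$tibfib)
  sfj <- supracondylar_plane(ph$femur, asm$frames$femoral)
  # symmetric phantom: normal lies in the sagittal plane
  expect_lt(abs(sfj$normal[1]), 1e-4)
  # truth plane from the analytic extremal points
  expect_lt(line_angle_deg(sfj$normal, ph$truth$primitives$sfj$normal), 0.05)

  # pitched construction changes mPDFA by the closed-form amount (90 - pitch)
  php <- cached_phantom("pitch5", phantom_spec(sfj_pitch_deg = 5, mesh_density_mm = 3))
  repp <- analyze_leg(php$femur, php$tibfib)
  expect_equal(unname(repp$angles_deg["mPDFA"]), 85, tolerance = 0.2 / 85)

  # border-band mode yields a plane within a degree of the three-point one
  sfj_band <- supracondylar_plane(ph$femur, asm$frames$femoral, mode = "border_band")
  expect_lt(line_angle_deg(sfj$normal, sfj_band$normal), 1.5)

  # missing trochlea: aggregated error naming the supracondylar stage
  noreg <- ph$femur
  noreg$regions$TROCHLEA <- NULL
  err <- tryCatch(analyze_leg(noreg, ph$tibfib), error = function(e) e)
  expect_s3_class(err, "legalign_error")
  expect_match(conditionMessage(err), "supracondylar")
})

test_that("plateau planes recover slopes and are tessellation invariant", {
  phs <- cached_phantom("slope7", phantom_spec(posterior_slope_medial_deg = 7,
                                               posterior_slope_lateral_deg = 7,
                                               mesh_density_mm = 3))
  pm <- plateau_plane(phs$tibfib, "MEDIAL")
  expect_lt(line_angle_deg(pm$normal, phs$truth$primitives$ptj_medial$normal),
            1e-3)
  # symmetric plateaus: combined plane equals each individual plane
  com <- plateau_plane(phs$tibfib, "COMBINED")
  expect_lt(line_angle_deg(com$normal, pm$normal), 1e-6)

  # refining only the medial tessellation leaves the combined plane in place
  # (area weighting), tested on asymmetric-slope patches
  mk <- function(n_med) {
    p1 <- legalign:::part_parallelogram(c(-23, 0, 0), c(11, 0, 0),
                                        14 * c(0, cos(0.12), sin(0.12)), n_med, n_med)
    p2 <- legalign:::part_parallelogram(c(23, 0, 0), c(11, 0, 0),
                                        14 * c(0, cos(0.03), sin(0.03)), 6, 6)
    verts <- rbind(p1$vertices, p2$vertices)
    faces <- rbind(p1$faces, p2$faces + nrow(p1$vertices))
    bone_model("TIBIA_FIBULA", "RIGHT", leg_mesh(verts, faces),
               list(MEDIAL_TIBIAL_PLATEAU = seq_len(nrow(p1$faces)),
                    LATERAL_TIBIAL_PLATEAU = nrow(p1$faces) + seq_len(nrow(p2$faces))),
               require_regions = FALSE)
  }
  c1 <- plateau_plane(mk(6), "COMBINED")
  c2 <- plateau_plane(mk(12), "COMBINED")
  expect_lt(line_angle_deg(c1$normal, c2$normal) * pi / 180, 1e-3)
})

test_that("angles track the construction parameters across phantom pairs", {
  cases <- list(
    list(key = "varus5c", spec = phantom_spec(femoral_varus_deg = 2,
                                              tibial_varus_deg = 3,
                                              mesh_density_mm = 3),
         expect = c(HKAA = 175, mLDFA = 92, mMPTA = 87)),
    list(key = "valgus8c", spec = phantom_spec(femoral_varus_deg = -5,
                                               tibial_varus_deg = -3,
                                               mesh_density_mm = 3),
         expect = c(HKAA = 188, mLDFA = 85, mMPTA = 93)),
    list(key = "slope7", spec = phantom_spec(posterior_slope_medial_deg = 7,
                                             posterior_slope_lateral_deg = 7,
                                             mesh_density_mm = 3),
         expect = c(mMPPTA = 83, mLPPTA = 83)),
    list(key = "slopemed", spec = phantom_spec(posterior_slope_medial_deg = 9,
                                               mesh_density_mm = 3),
         expect = c(mMPPTA = 81, mLPPTA = 90)),
    list(key = "torsion10", spec = phantom_spec(tibial_torsion_deg = 10,
                                                mesh_density_mm = 2),
         expect = c(TTA = 10)),
    list(key = "version15n", spec = phantom_spec(mesh_density_mm = 3),
         expect = c(FVA = 15, TTA = 25))
  )
  for (cs in cases) {
    ph <- cached_phantom(cs$key, cs$spec)
    rep <- analyze_leg(ph$femur, ph$tibfib)
    for (nm in names(cs$expect)) {
      expect_equal(unname(rep$angles_deg[nm]), unname(cs$expect[nm]),
                   tolerance = 0.2 / cs$expect[nm],
                   label = sprintf("%s[%s]", cs$key, nm))
    }
    # every case must also match its own analytic truth across all 8 angles
    expect_lt(max(abs(rep$angles_deg - ph$truth$angles_deg)), 0.2)
  }
})

test_that("medial-only slope change leaves the lateral slope angle unchanged", {
  base <- neutral_phantom()
  med <- cached_phantom("slopemed", phantom_spec(posterior_slope_medial_deg = 9,
                                                 mesh_density_mm = 3))
  r0 <- analyze_leg(base$femur, base$tibfib)
  r1 <- analyze_leg(med$femur, med$tibfib)
  expect_lt(abs(r1$angles_deg["mLPPTA"] - r0$angles_deg["mLPPTA"]), 0.05)
  expect_equal(unname(r1$angles_deg["mMPPTA"] - r0$angles_deg["mMPPTA"]), -9,
               tolerance = 0.05 / 9)
})

test_that("version and torsion ignore pure coronal deformity", {
  base <- neutral_phantom()
  varus <- cached_phantom("varus5c", phantom_spec(femoral_varus_deg = 2,
                                                  tibial_varus_deg = 3,
                                                  mesh_density_mm = 3))
  r0 <- analyze_leg(base$femur, base$tibfib)
  r1 <- analyze_leg(varus$femur, varus$tibfib)
  expect_lt(abs(r1$angles_deg["FVA"] - r0$angles_deg["FVA"]), 0.1)
  expect_lt(abs(r1$angles_deg["TTA"] - r0$angles_deg["TTA"]), 0.1)
})

test_that("direction labels resolve anteversion/retroversion and torsion sense", {
  retro <- cached_phantom("retro8", phantom_spec(femoral_version_deg = -8,
                                                 mesh_density_mm = 3))
  r <- analyze_leg(retro$femur, retro$tibfib)
  expect_identical(unname(r$directions["FVA"]), "RETROVERSION")
  expect_equal(unname(r$angles_deg["FVA"]), 8, tolerance = 0.2 / 8)

  internal <- cached_phantom("torsionm10", phantom_spec(tibial_torsion_deg = -10,
                                                        mesh_density_mm = 3))
  r2 <- analyze_leg(internal$femur, internal$tibfib)
  expect_identical(unname(r2$directions["TTA"]), "INTERNAL")

  # labels survive mirroring
  retro_l <- cached_phantom("retro8l", phantom_spec(femoral_version_deg = -8,
                                                    side = "LEFT",
                                                    mesh_density_mm = 3))
  rl <- analyze_leg(retro_l$femur, retro_l$tibfib)
  expect_identical(unname(rl$directions["FVA"]), "RETROVERSION")
})

test_that("mirrored left legs reproduce right-leg angles", {
  r_right <- analyze_leg(neutral_phantom()$femur, neutral_phantom()$tibfib)
  phl <- cached_phantom("left3", phantom_spec(side = "LEFT", mesh_density_mm = 3))
  r_left <- analyze_leg(phl$femur, phl$tibfib)
  expect_lt(max(abs(r_right$angles_deg - r_left$angles_deg)), 1e-3)
  expect_identical(r_right$directions, r_left$directions)
})

test_that("analyze_leg is deterministic and extension policies behave", {
  ph <- neutral_phantom()
  r1 <- analyze_leg(ph$femur, ph$tibfib)
  r2 <- analyze_leg(ph$femur, ph$tibfib)
  expect_identical(r1$angles_deg, r2$angles_deg)
  expect_identical(r1$metadata$femur_digest, r2$metadata$femur_digest)

  flexed <- cached_phantom("flex10", phantom_spec(knee_flexion_deg = 10,
                                                  mesh_density_mm = 3))
  expect_error(analyze_leg(flexed$femur, flexed$tibfib,
                           legalign_config(angles.extension_policy = "strict")),
               class = "legalign_extension_error")
  expect_warning(
    r_ign <- analyze_leg(flexed$femur, flexed$tibfib,
                         legalign_config(angles.extension_policy = "ignore")),
    "not extended")
  expect_equal(unname(r_ign$extension_residual_deg), 10, tolerance = 0.01)

  # tidy/glance/autoplot surfaces
  td <- tidy(r1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  gl <- glance(r1)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("HKAA", "FVA_direction", "extension_residual_deg") %in% names(gl)))
  expect_s3_class(autoplot(r1), "ggplot")
})
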