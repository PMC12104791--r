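# Shape fitting and projection primitives.

test_that("region_points returns area-weighted face centroids", {
  tri <- leg_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5),
                        c(6, 5, 5), c(5, 6, 5), c(9, 9, 9), c(9, 8, 7)),
                  rbind(c(1, 2, 3), c(4, 5, 6), c(1, 2, 4), c(5, 6, 7)))
  model <- bone_model("FEMUR", "RIGHT", tri, list(TROCHLEA = c(1L, 2L)),
                      require_regions = FALSE)
  rp <- region_points(model, "TROCHLEA")
  # two equal-area coplanar unit right triangles: centroids at (1/3,1/3) marks
  expect_equal(unname(rp$points[1, ]), c(1, 1, 0) / 3, tolerance = 1e-12)
  expect_equal(unname(rp$weights), c(0.5, 0.5))
  rv <- region_points(model, "TROCHLEA", "VERTICES")
  expect_equal(nrow(rv$points), 6)
  expect_true(all(rv$weights == 1))
  expect_error(region_points(model, "FEMORAL_HEAD"),
               class = "legalign_label_error")
})

test_that("surface centroids match closed forms (square, sphere, cap)", {
  sq <- leg_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(9, 9, 9)),
                 rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 5), c(2, 3, 5)))
  m <- bone_model("FEMUR", "RIGHT", sq, list(TROCHLEA = c(1L, 2L)),
                  require_regions = FALSE)
  expect_equal(surface_centroid(m, "TROCHLEA"), c(0.5, 0.5, 0), tolerance = 1e-12)

  # hemispherical cap: area centroid offset along the pole is R(1+cos psi0)/2
  ctr <- c(3, -2, 7); R <- 20; psi0 <- pi / 2
  cap <- legalign:::part_sphere_cap(ctr, R, c(0, 0, 1), psi0, 0.75)
  mesh <- leg_mesh(cap$vertices, cap$faces)
  mc <- bone_model("FEMUR", "RIGHT", mesh,
                   list(FEMORAL_HEAD = seq_len(nrow(mesh$faces))),
                   require_regions = FALSE)
  got <- surface_centroid(mc, "FEMORAL_HEAD")
  expect_lt(max(abs(got - oracle_cap_centroid(ctr, R, c(0, 0, 1), psi0))), 0.02)
})

test_that("sphere fit recovers exact and partial-coverage samples", {
  ctr <- c(10, -20, 30); R <- 25
  pts <- sphere_sector_points(ctr, R, psi_max = 0.9 * pi)  # full sector
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center - ctr)), 1e-9)
  expect_lt(abs(fit$radius - R), 1e-9)
  expect_lt(fit$rms_mm, 1e-9)

  hemi <- sphere_sector_points(ctr, R, psi_max = pi / 2)  # femoral-head-like
  fit <- fit_sphere(hemi)
  expect_lt(max(abs(fit$center - ctr)), 1e-6)
  expect_lt(abs(fit$radius - R), 1e-6)
})

test_that("noisy sphere fit agrees with a truth-started Gauss-Newton oracle", {
  ctr <- c(10, -20, 30); R <- 25
  set.seed(101)
  pts <- sphere_sector_points(ctr, R, n_psi = 40, n_phi = 50, psi_max = 2)
  pts <- pts + matrix(rnorm(length(pts), sd = 0.1), ncol = 3)
  w <- rep(1, nrow(pts))
  fit <- fit_sphere(pts)
  orc <- oracle_sphere_gn(pts, w, ctr, R)
  expect_lt(max(abs(fit$center - orc$center)), 1e-4)
  expect_lt(abs(fit$radius - orc$radius), 1e-4)
})

test_that("plane fit recovers exact, symmetric-noise and tilted planes", {
  set.seed(7)
  xy <- cbind(runif(200, -10, 10), runif(200, -10, 10))
  flat <- cbind(xy, 3)
  pl <- fit_plane(flat)
  expect_lt(line_angle_deg(pl$normal, c(0, 0, 1)), 1e-9)
  expect_lt(pl$rms_mm, 1e-9)

  # symmetric +/- eps perturbation: same plane, rms = eps
  eps <- 0.25
  pert <- rbind(cbind(xy, 3 + eps), cbind(xy, 3 - eps))
  pl2 <- fit_plane(pert)
  expect_lt(line_angle_deg(pl2$normal, c(0, 0, 1)), 1e-9)
  expect_equal(pl2$rms_mm, eps, tolerance = 1e-12)

  # plateau sloped 7 degrees about the ML (x) axis
  ang <- 7 * pi / 180
  R <- legalign:::rotation_about_axis(c(1, 0, 0), ang)
  tilted <- flat %*% t(R)
  pl3 <- fit_plane(tilted, orient_hint = c(0, 0, 1))
  expect_lt(abs(line_angle_deg(pl3$normal, c(0, 0, 1)) - 7), 1e-6)

  expect_error(fit_plane(cbind(1:10, 2 * (1:10), 3 * (1:10))),
               class = "legalign_degeneracy_error")
})

test_that("cylinder fit recovers two-band condylar geometry", {
  axis <- c(1, 0, 0); pt <- c(0, 5, -3); R <- 22
  pts <- cylinder_band_points(pt, axis, R)
  fit <- fit_cylinder(pts)
  expect_lt(line_angle_deg(fit$axis$direction, axis) * pi / 180, 1e-6)
  expect_lt(abs(fit$radius - R), 1e-6)
  expect_lt(fit$rms_mm, 1e-9)
  # fitted axis passes through the true axis
  rel <- fit$axis$point - pt
  expect_lt(sqrt(sum((rel - sum(rel * axis) * axis)^2)), 1e-6)
})

test_that("noisy cylinder fit matches a truth-started refit oracle", {
  axis <- unitize_test <- c(1, 0, 0); pt <- c(0, 5, -3); R <- 22
  set.seed(202)
  pts <- cylinder_band_points(pt, axis, R, n_s = 12, n_t = 60)
  pts <- pts + matrix(rnorm(length(pts), sd = 0.1), ncol = 3)
  w <- rep(1, nrow(pts))
  fit <- fit_cylinder(pts)
  orc <- oracle_cylinder_refit(pts, w, pt, axis, R)
  expect_lt(line_angle_deg(fit$axis$direction, orc$direction) * pi / 180, 1e-3)
  expect_lt(abs(fit$radius - orc$radius), 1e-2)
})

test_that("cylinder fit on spherical points raises a degeneracy error", {
  set.seed(3)
  u <- matrix(rnorm(1800), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 25
  expect_error(fit_cylinder(u), class = "legalign_degeneracy_error")
})

test_that("point and direction projections follow the worked examples", {
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(project_point_along(c(1, 1, 5), pl, c(0, 0, 1)), c(1, 1, 0))
  expect_equal(project_point_along(c(2, -3, 0), pl, c(0, 0, 1)), c(2, -3, 0))
  # oblique projection solved by hand: from (0,0,2) along (0,1,1)/sqrt(2)
  expect_equal(project_point_along(c(0, 0, 2), pl, c(0, 1, 1) / sqrt(2)),
               c(0, -2, 0), tolerance = 1e-12)
  expect_error(project_point_along(c(0, 0, 2), pl, c(1, 0, 0)),
               class = "legalign_projection_error")

  d <- c(1, 0, 0)
  expect_equal(project_direction_onto_plane(d, c(0, 0, 1)), d)
  d45 <- c(1, 0, 1) / sqrt(2)
  expect_equal(project_direction_onto_plane(d45, c(0, 0, 1)), c(1, 0, 0))
  expect_error(project_direction_onto_plane(c(0, 0, 1), c(0, 0, 1)),
               class = "legalign_projection_error")

  # property: projection is orthogonal to the normal and the angle to the
  # plane complements the angle to the projection
  set.seed(11)
  for (i in 1:50) {
    d <- rnorm(3); n <- rnorm(3)
    n <- n / sqrt(sum(n^2))
    if (line_angle_deg(d, n) < 1) next
    pr <- project_direction_onto_plane(d, n)
    expect_lt(abs(sum(pr * n)), 1e-9)
    du <- d / sqrt(sum(d^2))
    ang_dp <- acos(pmin(1, abs(sum(du * pr))))
    ang_dn <- acos(pmin(1, abs(sum(du * n))))
    expect_lt(abs((ang_dp + ang_dn) - pi / 2), 1e-9)
  }
})

test_that("in-plane angles follow the stated convention and reversal identity", {
  expect_equal(angle_in_plane(c(1, 2, 0.5), c(1, 2, 0.5), c(0, 0, 1)), 360)
  expect_equal(angle_in_plane(c(0, 0, 1), c(1, 0, 0), c(0, -1, 0)), 90)
  expect_equal(angle_in_plane(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1)), 180)
  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3); n <- rnorm(3)
    s <- (angle_in_plane(a, b, n) + angle_in_plane(b, a, n)) %% 360
    expect_lt(min(s, 360 - s), 1e-9)
  }
})

test_that("line-mesh intersection handles closed shells, misses and shared edges", {
  tube <- legalign:::part_cylinder(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                                   10, seq(-15, 15, by = 2),
                                   seq(-pi, pi, length.out = 40), caps = TRUE)
  mesh <- leg_mesh(tube$vertices, tube$faces)
  hits <- line_mesh_intersections(line3(c(0, 0, 0), c(0, 0, 1)), mesh)
  expect_equal(nrow(hits), 2)
  expect_equal(colMeans(hits), c(x = 0, y = 0, z = 0), tolerance = 1e-9)

  miss <- line_mesh_intersections(line3(c(100, 100, 0), c(0, 0, 1)), mesh)
  expect_equal(nrow(miss), 0)

  # two triangles sharing an edge; a line through the shared edge midpoint
  # must yield one deduplicated point
  m2 <- leg_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(4, 4, 4)),
                 rbind(c(1, 2, 3), c(2, 4, 3), c(1, 2, 5), c(3, 4, 5)))
  hits <- line_mesh_intersections(line3(c(0.5, 0.5, -5), c(0, 0, 1)), m2,
                                  face_subset = c(1L, 2L))
  expect_equal(nrow(hits), 1)
  expect_equal(unname(hits[1, ]), c(0.5, 0.5, 0))
})

test_that("fits are rigid-transform equivariant with invariant residuals", {
  set.seed(77)
  ctr <- c(5, 5, 5); R <- 18
  sp_pts <- sphere_sector_points(ctr, R, psi_max = 2.2)
  sp_pts <- sp_pts + matrix(rnorm(length(sp_pts), sd = 0.05), ncol = 3)
  cy_pts <- cylinder_band_points(c(0, 1, 2), c(1, 0, 0), 22)
  cy_pts <- cy_pts + matrix(rnorm(length(cy_pts), sd = 0.05), ncol = 3)
  pl_pts <- cbind(runif(100, -10, 10), runif(100, -10, 10), rnorm(100, sd = 0.05))

  for (rep in 1:3) {
    tf <- random_rigid()
    s1 <- fit_sphere(sp_pts); s2 <- fit_sphere(apply_rigid(tf, sp_pts))
    expect_lt(max(abs(apply_rigid(tf, s1$center) - s2$center)), 1e-6)
    expect_lt(abs(s1$rms_mm - s2$rms_mm), 1e-9)

    c1 <- fit_cylinder(cy_pts); c2 <- fit_cylinder(apply_rigid(tf, cy_pts))
    expect_lt(line_angle_deg(as.numeric(tf$R %*% c1$axis$direction),
                             c2$axis$direction) * pi / 180, 1e-8)
    expect_lt(abs(c1$rms_mm - c2$rms_mm), 1e-9)

    p1 <- fit_plane(pl_pts); p2 <- fit_plane(apply_rigid(tf, pl_pts))
    expect_lt(line_angle_deg(as.numeric(tf$R %*% p1$normal), p2$normal) * pi / 180,
              1e-8)
    expect_lt(abs(p1$rms_mm - p2$rms_mm), 1e-9)
  }
})
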