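# Independent oracles and hand-built fixtures. Everything here is kept
# deliberately naive (plain Gauss-Newton / BFGS, explicit arithmetic) so it
# stays independent of the package's fitting path.

# Plain Gauss-Newton sphere refit with analytic Jacobian, started from given
# parameters (typically the construction truth).
oracle_sphere_gn <- function(points, weights, center0, radius0, iters = 60) {
  p <- as.matrix(points); w <- weights
  par <- c(center0, radius0)
  for (i in seq_len(iters)) {
    dc <- sweep(p, 2, par[1:3])
    d <- sqrt(rowSums(dc^2))
    r <- d - par[4]
    J <- cbind(-dc / d, -1)
    A <- crossprod(J * w, J)
    g <- crossprod(J * w, r)
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) break
    par <- par - as.numeric(step)
    if (max(abs(step)) < 1e-14) break
  }
  list(center = par[1:3], radius = par[4])
}

# Cylinder refit by BFGS over (axis point 3, axis direction 3, radius),
# normalizing the direction inside the objective; started from truth.
oracle_cylinder_refit <- function(points, weights, point0, dir0, radius0) {
  p <- as.matrix(points); w <- weights
  obj <- function(par) {
    a <- par[4:6] / sqrt(sum(par[4:6]^2))
    rel <- sweep(p, 2, par[1:3])
    proj <- as.numeric(rel %*% a)
    d <- sqrt(pmax(rowSums(rel^2) - proj^2, 0)) - par[7]
    sum(w * d^2)
  }
  fit <- stats::optim(c(point0, dir0, radius0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  dir <- fit$par[4:6] / sqrt(sum(fit$par[4:6]^2))
  list(point = fit$par[1:3], direction = dir, radius = fit$par[7])
}

# Acute angle between two lines' directions, degrees.
line_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, ca)) * 180 / pi
}

# Exact area centroid of a spherical cap surface of half-angle psi0 about
# `pole` on a sphere (center, R): centroid offset along the pole is
# R (1 + cos(psi0)) / 2.
oracle_cap_centroid <- function(center, R, pole, psi0) {
  center + pole * R * (1 + cos(psi0)) / 2
}

# Sample points exactly on a sphere sector (deterministic grid).
sphere_sector_points <- function(center, R, n_psi = 25, n_phi = 60,
                                 psi_max = pi / 2) {
  psi <- seq(psi_max / n_psi, psi_max, length.out = n_psi)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-1]
  g <- expand.grid(psi = psi, phi = phi)
  cbind(center[1] + R * sin(g$psi) * cos(g$phi),
        center[2] + R * sin(g$psi) * sin(g$phi),
        center[3] + R * cos(g$psi))
}

# Sample exact points from two arc-bands of a cylinder (condyle-like).
cylinder_band_points <- function(point, axis, radius, band_centers = c(-24, 24),
                                 band_half = 8, arc = c(-45, 120) * pi / 180,
                                 n_s = 9, n_t = 40) {
  B <- cbind(axis)
  # complete an orthonormal basis around `axis`
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  pts <- NULL
  for (bc in band_centers) {
    s <- seq(bc - band_half, bc + band_half, length.out = n_s)
    t <- seq(arc[1], arc[2], length.out = n_t)
    g <- expand.grid(s = s, t = t)
    pts <- rbind(pts, t(vapply(seq_len(nrow(g)), function(i) {
      point + g$s[i] * axis + radius * (cos(g$t[i]) * u + sin(g$t[i]) * v)
    }, numeric(3))))
  }
  pts
}

# A random rigid transform (rotation + translation), seeded by the caller.
random_rigid <- function(scale = 200) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = scale))
}

apply_rigid <- function(tf, pts) {
  if (is.null(dim(pts))) as.numeric(tf$R %*% pts + tf$t)
  else sweep(pts %*% t(tf$R), 2, -tf$t)
}

# Hand-built minimal tibia/fibula: plateaus as flat rectangles (2 triangles
# each) with controllable sizes/heights, a plafond and two malleolar facets.
rect_part <- function(center, half_u, half_v) {
  v <- rbind(center - half_u - half_v, center + half_u - half_v,
             center + half_u + half_v, center - half_u + half_v)
  list(vertices = v, faces = rbind(c(1, 2, 3), c(1, 3, 4)))
}

hand_tibfib <- function(medial_plateau = rect_part(c(-20, 0, 0), c(10, 0, 0), c(0, 12, 0)),
                        lateral_plateau = rect_part(c(20, 0, 0), c(10, 0, 0), c(0, 12, 0)),
                        plafond = rect_part(c(0, 0, -300), c(12, 0, 0), c(0, 10, 0)),
                        mall_m = rect_part(c(-25, 0, -300), c(0, 0, 6), c(0, 5, 0)),
                        mall_l = rect_part(c(25, 0, -300), c(0, 0, 6), c(0, 5, 0)),
                        side = "RIGHT") {
  parts <- list(medial_plateau, lateral_plateau, plafond, mall_m, mall_l)
  names(parts) <- c("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU",
                    "TIBIAL_PLAFOND", "MEDIAL_MALLEOLUS_FACET",
                    "LATERAL_MALLEOLUS_FACET")
  vofs <- 0L; fofs <- 0L
  verts <- NULL; faces <- NULL; regions <- list()
  for (nm in names(parts)) {
    p <- parts[[nm]]
    verts <- rbind(verts, p$vertices)
    faces <- rbind(faces, p$faces + vofs)
    regions[[nm]] <- fofs + seq_len(nrow(p$faces))
    vofs <- vofs + nrow(p$vertices); fofs <- fofs + nrow(p$faces)
  }
  bone_model("TIBIA_FIBULA", side, leg_mesh(verts, faces), regions)
}

# Memoized phantoms shared across test files (coarse, fast).
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(spec)
  }
  .phantom_cache[[key]]
}

neutral_phantom <- function(density = 3) {
  cached_phantom(paste0("neutral", density), phantom_spec(mesh_density_mm = density))
}
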