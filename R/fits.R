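# Orthogonal-distance (geometric) fits of plane, sphere and cylinder to
# weighted point sets. Algebraic solutions initialize; Levenberg-Marquardt
# (minpack.lm) refines the sphere and cylinder to the geometric optimum.
# Weighted rms is reported as sqrt(sum(w d^2) / sum(w)).

as_weighted_points <- function(points, weights = NULL) {
  if (is.list(points) && !is.null(points$points)) {
    weights <- points$weights
    points <- points$points
  }
  points <- as.matrix(points)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  stopifnot(nrow(points) == length(weights), all(weights >= 0))
  list(points = points, weights = as.numeric(weights))
}

weighted_rms <- function(d, w) sqrt(sum(w * d^2) / sum(w))

#' Total-least-squares plane fit
#'
#' Minimizes the weighted sum of squared orthogonal distances. The normal is
#' the smallest-eigenvalue eigenvector of the weighted scatter matrix; its
#' sign is aligned with `orient_hint` when given.
#'
#' @param points n x 3 matrix, or a list with `points` and `weights`
#'   (as returned by [region_points()]).
#' @param weights optional non-negative weights.
#' @param orient_hint optional direction the normal should point along.
#' @return a [plane3()] with `rms_mm`.
#' @export
fit_plane <- function(points, weights = NULL, orient_hint = NULL) {
  wp <- as_weighted_points(points, weights)
  p <- wp$points; w <- wp$weights
  if (nrow(p) < 3) {
    stop_legalign("plane fit needs at least 3 points", "legalign_degeneracy_error")
  }
  ctr <- colSums(p * w) / sum(w)
  q <- sweep(p, 2, ctr)
  S <- crossprod(q * sqrt(w))
  eg <- eigen(S, symmetric = TRUE)
  # collinear points: two near-zero eigenvalues
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-12) {
    stop_legalign("points are collinear; plane fit degenerate",
                  "legalign_degeneracy_error")
  }
  n <- eg$vectors[, 3]
  if (!is.null(orient_hint) && sum(n * orient_hint) < 0) n <- -n
  d <- as.numeric(q %*% n)
  plane3(ctr, n, weighted_rms(d, w))
}

# Algebraic (Kasa-style) sphere fit: linear least squares on
# |p|^2 = 2 c.p + (r^2 - |c|^2).
sphere_fit_algebraic <- function(p, w) {
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sw <- sqrt(w)
  sol <- tryCatch(qr.solve(A * sw, b * sw), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = ctr, radius = sqrt(r2))
}

#' Geometric sphere fit
#'
#' Minimizes the weighted sum of squared orthogonal distances
#' `(|p - c| - r)^2`; an algebraic fit initializes a Levenberg-Marquardt
#' refinement.
#'
#' @inheritParams fit_plane
#' @param tol gradient/step convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `sphere_fit`: `center`, `radius`, `rms_mm`.
#' @export
fit_sphere <- function(points, weights = NULL, tol = 1e-10, max_iter = 200) {
  wp <- as_weighted_points(points, weights)
  p <- wp$points; w <- wp$weights
  if (nrow(p) < 4) {
    stop_legalign("sphere fit needs at least 4 points", "legalign_degeneracy_error")
  }
  # coplanarity check: smallest scatter eigenvalue ~ 0 means center unidentifiable
  ctr0 <- colSums(p * w) / sum(w)
  q <- sweep(p, 2, ctr0)
  eg <- eigen(crossprod(q * sqrt(w)), symmetric = TRUE)
  if (eg$values[3] <= max(eg$values[1], 1) * 1e-14) {
    stop_legalign("points are coplanar; sphere fit degenerate",
                  "legalign_degeneracy_error")
  }
  init <- sphere_fit_algebraic(p, w)
  if (is.null(init)) {
    stop_legalign("algebraic sphere initialization failed", "legalign_degeneracy_error")
  }
  sw <- sqrt(w)
  resid <- function(par) {
    d <- sqrt(rowSums(sweep(p, 2, par[1:3])^2))
    sw * (d - par[4])
  }
  fit <- minpack.lm::nls.lm(
    par = c(init$center, init$radius), fn = resid,
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol, gtol = tol,
                                         maxiter = as.integer(max_iter)))
  par <- gauss_newton_polish(resid, fit$par)
  if (par[4] <= 0) {
    stop_legalign("sphere fit collapsed to non-positive radius",
                  "legalign_degeneracy_error")
  }
  d <- sqrt(rowSums(sweep(p, 2, par[1:3])^2)) - par[4]
  structure(list(center = par[1:3], radius = par[4], rms_mm = weighted_rms(d, w),
                 niter = fit$niter),
            class = "sphere_fit")
}

# Algebraic circle fit in 2D (Kasa).
circle_fit_algebraic <- function(xy, w) {
  A <- cbind(2 * xy, 1)
  b <- rowSums(xy^2)
  sw <- sqrt(w)
  sol <- tryCatch(qr.solve(A * sw, b * sw), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- sol[1:2]
  r2 <- sol[3] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = ctr, radius = sqrt(r2))
}

# Orthonormal basis completing a unit vector.
complete_basis <- function(z) {
  z <- unitize(z)
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(ref, z))
  v <- cross3(z, u)
  cbind(u, v, z)
}

#' Geometric cylinder fit
#'
#' Fits an infinite cylinder by minimizing weighted squared orthogonal
#' distances to the surface. Each principal direction of the point scatter is
#' tried as an axis candidate (projected circle fit in the orthogonal plane);
#' the best candidate initializes a Levenberg-Marquardt refinement over axis
#' direction (2 angles), axis offset (2) and radius. A near-spherical point
#' set leaves the axis unidentifiable and raises a degeneracy error (Jacobian
#' condition check).
#'
#' @inheritParams fit_sphere
#' @return object of class `cylinder_fit`: `axis` ([line3()]), `radius`,
#'   `rms_mm`, `niter`.
#' @export
fit_cylinder <- function(points, weights = NULL, tol = 1e-10, max_iter = 200) {
  wp <- as_weighted_points(points, weights)
  p <- wp$points; w <- wp$weights
  if (nrow(p) < 6) {
    stop_legalign("cylinder fit needs at least 6 points", "legalign_degeneracy_error")
  }
  ctr <- colSums(p * w) / sum(w)
  q <- sweep(p, 2, ctr)
  eg <- eigen(crossprod(q * sqrt(w)) / sum(w), symmetric = TRUE)

  # candidate axes: all principal directions (incl. the smallest-variance one)
  best <- NULL
  for (k in 1:3) {
    a <- eg$vectors[, k]
    B <- complete_basis(a)
    xy <- q %*% B[, 1:2]
    cf <- circle_fit_algebraic(xy, w)
    if (is.null(cf)) next
    d <- sqrt((xy[, 1] - cf$center[1])^2 + (xy[, 2] - cf$center[2])^2) - cf$radius
    sc <- weighted_rms(d, w)
    if (is.null(best) || sc < best$score) {
      best <- list(axis = a, B = B, center2d = cf$center, radius = cf$radius,
                   score = sc)
    }
  }
  if (is.null(best)) {
    stop_legalign("cylinder initialization failed", "legalign_degeneracy_error")
  }

  # parameters: (alpha, beta) tilt the axis; (u0, v0) offset in the plane
  # orthogonal to the initial axis; r radius.
  B0 <- best$B
  sw <- sqrt(w)
  par0 <- c(0, 0, best$center2d[1], best$center2d[2], best$radius)
  geom <- function(par) {
    a <- unitize(as.numeric(B0 %*% c(sin(par[1]), sin(par[2]),
                                     sqrt(max(0, 1 - sin(par[1])^2 - sin(par[2])^2)))))
    c0 <- ctr + as.numeric(B0 %*% c(par[3], par[4], 0))
    list(axis_dir = a, axis_point = c0, r = par[5])
  }
  resid <- function(par) {
    g <- geom(par)
    rel <- sweep(p, 2, g$axis_point)
    proj <- as.numeric(rel %*% g$axis_dir)
    d <- sqrt(pmax(rowSums(rel^2) - proj^2, 0)) - g$r
    sw * d
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid,
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol, gtol = tol,
                                         maxiter = as.integer(max_iter)))
  if (fit$info %in% c(0, 9) && fit$niter >= max_iter) {
    stop_legalign(sprintf("cylinder fit did not converge in %d iterations (info %d)",
                          fit$niter, fit$info),
                  "legalign_fit_error", niter = fit$niter, deviance = fit$deviance)
  }
  fit$par <- gauss_newton_polish(resid, fit$par)
  g <- geom(fit$par)
  if (g$r <= 0) {
    stop_legalign("cylinder fit collapsed to non-positive radius",
                  "legalign_degeneracy_error")
  }
  # identifiability: the Jacobian must have full rank at the solution, and a
  # sphere must not explain the points as well as the cylinder does (a
  # near-spherical set leaves the axis direction meaningless).
  J <- numeric_jacobian(resid, fit$par)
  sv <- svd(J, nu = 0, nv = 0)$d
  if (sv[1] <= 0 || sv[length(sv)] / sv[1] < 1e-8) {
    stop_legalign("cylinder axis unidentifiable (near-spherical point set)",
                  "legalign_degeneracy_error")
  }
  cyl_rms <- weighted_rms(resid(fit$par) / sw, w)
  sph <- tryCatch(fit_sphere(p, w, tol = tol, max_iter = max_iter),
                  error = function(e) NULL)
  if (!is.null(sph) && sph$rms_mm <= cyl_rms * 1.05 + 1e-12) {
    stop_legalign("cylinder axis unidentifiable (a sphere fits the points as well)",
                  "legalign_degeneracy_error")
  }
  rel <- sweep(p, 2, g$axis_point)
  proj <- as.numeric(rel %*% g$axis_dir)
  d <- sqrt(pmax(rowSums(rel^2) - proj^2, 0)) - g$r
  structure(list(axis = line3(g$axis_point, g$axis_dir), radius = g$r,
                 rms_mm = weighted_rms(d, w), niter = fit$niter),
            class = "cylinder_fit")
}

numeric_jacobian <- function(fn, par, h = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

# A few damped Gauss-Newton steps (central-difference Jacobian) to polish an
# LM solution to machine precision; keeps fitted axes reproducible across
# rigid transforms of the data.
gauss_newton_polish <- function(fn, par, iters = 4) {
  for (i in seq_len(iters)) {
    f0 <- fn(par)
    J <- matrix(0, length(f0), length(par))
    for (j in seq_along(par)) {
      h <- 1e-7 * max(1, abs(par[j]))
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
    }
    step <- tryCatch(qr.solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par + step
    if (sum(fn(cand)^2) <= sum(f0^2)) par <- cand else break
    if (max(abs(step)) < 1e-14) break
  }
  par
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.3f, %.3f, %.3f) r %.3f mm, rms %.2g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_mm))
  invisible(x)
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("<cylinder_fit> axis dir (%.4f, %.4f, %.4f) r %.3f mm, rms %.2g mm\n",
              x$axis$direction[1], x$axis$direction[2], x$axis$direction[3],
              x$radius, x$rms_mm))
  invisible(x)
}

#' @method tidy sphere_fit
#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble::tibble(term = c("center_x", "center_y", "center_z", "radius"),
                 estimate = c(x$center, x$radius))
}

#' @method glance sphere_fit
#' @export
glance.sphere_fit <- function(x, ...) {
  tibble::tibble(radius_mm = x$radius, rms_mm = x$rms_mm, niter = x$niter)
}

#' @method tidy cylinder_fit
#' @export
tidy.cylinder_fit <- function(x, ...) {
  tibble::tibble(term = c("axis_point_x", "axis_point_y", "axis_point_z",
                          "axis_dir_x", "axis_dir_y", "axis_dir_z", "radius"),
                 estimate = c(x$axis$point, x$axis$direction, x$radius))
}

#' @method glance cylinder_fit
#' @export
glance.cylinder_fit <- function(x, ...) {
  tibble::tibble(radius_mm = x$radius, rms_mm = x$rms_mm, niter = x$niter)
}
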