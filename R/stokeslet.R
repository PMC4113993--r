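#' Planar velocity-field snapshot
#'
#' Container for one gridded (or scattered) planar velocity snapshot, the
#' unit of PIV-like data consumed by the flow-fitting routines.
#'
#' @param x,y point coordinates (micrometres).
#' @param u,v velocity components (micrometres per second).
#' @param t time stamp of the snapshot (seconds).
#' @return An object of class `velocity_field`: a list with elements
#'   `points` (n x 2 matrix), `u` (n x 2 matrix) and `t`.
#' @export
velocity_field <- function(x, y, u, v, t = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y)
  u <- as.numeric(u); v <- as.numeric(v)
  n <- length(x)
  if (length(y) != n || length(u) != n || length(v) != n)
    stop("x, y, u, v must have equal length")
  vals <- c(x, y, u, v)
  if (!all(is.finite(vals))) stop("velocity field must contain finite values only")
  structure(list(points = cbind(x = x, y = y), u = cbind(u = u, v = v), t = t),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("Planar velocity field:", nrow(x$points), "points")
  if (is.finite(x$t)) cat(sprintf(", t = %g s", x$t))
  cat(sprintf(", rms speed %.3g um/s\n", sqrt(mean(rowSums(x$u^2)))))
  invisible(x)
}

#' Evaluate a Stokeslet (point-force) flow field
#'
#' Velocity of the flow driven by a point force in Stokes flow, evaluated in
#' the plane of the force: `u(x) = (1/r) (I + rhat rhat) . G` with
#' the displacement from the force point being `x - x0` with length `r`.
#' `G = F / (8 pi mu)` is the reduced force in um^2/s, so the
#' returned velocities are in um/s. The field decays as 1/r and the on-axis
#' speed is exactly twice the off-axis speed at equal distance.
#'
#' @param G reduced force vector `F/(8 pi mu)`, length 2, um^2/s.
#' @param x0 position of the point force, length 2, um.
#' @param points n x 2 matrix of evaluation points, um.
#' @return n x 2 matrix of velocities, um/s.
#' @export
evaluate_stokeslet <- function(G, x0, points) {
  points <- rbind(points)
  rx <- points[, 1] - x0[1]
  ry <- points[, 2] - x0[2]
  r2 <- rx * rx + ry * ry
  if (any(r2 == 0)) stop("evaluation point coincides with the Stokeslet position")
  r <- sqrt(r2)
  rg <- (rx * G[1] + ry * G[2]) / r2   # (rhat . G) / r
  cbind(u = (G[1] + rg * rx) / r, v = (G[2] + rg * ry) / r)
}

# Exact linear least-squares solve for G at fixed x0, plus the residual
# sum of squares. Returns list(G, rss).
stokeslet_linear_solve <- function(field, x0) {
  p <- field$points
  rx <- p[, 1] - x0[1]; ry <- p[, 2] - x0[2]
  r2 <- rx * rx + ry * ry
  if (any(r2 < 1e-16)) return(list(G = c(NA, NA), rss = 1e300))
  r <- sqrt(r2)
  # u_model = M(x0) G, with 2x2 blocks M_i = (1/r)(I + rhat rhat)
  a11 <- (1 + rx * rx / r2) / r
  a12 <- (rx * ry / r2) / r
  a22 <- (1 + ry * ry / r2) / r
  A <- rbind(cbind(a11, a12), cbind(a12, a22))
  b <- c(field$u[, 1], field$u[, 2])
  fit <- tryCatch(qr.solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(fit)) return(list(G = c(NA, NA), rss = 1e300))
  G <- as.numeric(fit)
  list(G = G, rss = sum((A %*% G - b)^2))
}

#' Fit a Stokeslet to a velocity snapshot
#'
#' Least-squares fit of a point-force flow to a planar velocity field, with
#' the force position `x0` and reduced force vector `G` as free parameters.
#' For any fixed `x0` the `G` sub-problem is linear and solved exactly; the
#' remaining two-dimensional search over `x0` uses Nelder-Mead started from
#' the location of maximum measured speed (and from `init$x0` if supplied),
#' keeping the best of the starts.
#'
#' @param field a [velocity_field].
#' @param init optional initial guess, a list with element `x0`.
#' @return An object of class `stokeslet_fit` with elements `x0`, `G`
#'   (um^2/s), `residual` (RMS velocity misfit, um/s), `rss`, `converged`
#'   and the input `field`. Methods: [coef.stokeslet_fit()],
#'   [predict.stokeslet_fit()], [residuals.stokeslet_fit()].
#' @export
fit_stokeslet <- function(field, init = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  n <- nrow(field$points)
  if (n < 10) stop("need at least 10 grid points to fit a Stokeslet")
  sp <- svd(scale(field$points, scale = FALSE))$d
  if (sp[2] < 1e-10 * sp[1]) {
    out <- structure(list(x0 = c(NA, NA), G = c(NA, NA), residual = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          failure = "degenerate geometry: collinear points",
                          field = field), class = "stokeslet_fit")
    return(out)
  }
  obj <- function(x0) stokeslet_linear_solve(field, x0)$rss
  speed <- sqrt(rowSums(field$u^2))
  spacing <- stats::median(sqrt(rowSums(
    (field$points - field$points[c(2:n, 1), , drop = FALSE])^2)))
  # offset the start from the grid node so the 1/r kernel is evaluable there
  starts <- list(field$points[which.max(speed), ] + 0.25 * spacing)
  if (!is.null(init) && !is.null(init$x0)) starts <- c(list(init$x0), starts)
  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    # polish with a restart; Nelder-Mead can stall on narrow valleys
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  sol <- stokeslet_linear_solve(field, best$par)
  structure(list(x0 = as.numeric(best$par), G = sol$G,
                 residual = sqrt(sol$rss / n), rss = sol$rss,
                 converged = best$convergence == 0, failure = NULL,
                 field = field),
            class = "stokeslet_fit")
}

#' @export
print.stokeslet_fit <- function(x, ...) {
  cat("Stokeslet fit\n")
  if (!is.null(x$failure)) {
    cat("  FAILED:", x$failure, "\n")
    return(invisible(x))
  }
  cat(sprintf("  x0 = (%.3f, %.3f) um\n", x$x0[1], x$x0[2]))
  cat(sprintf("  G  = (%.4g, %.4g) um^2/s, |G| = %.4g um^2/s\n",
              x$G[1], x$G[2], sqrt(sum(x$G^2))))
  cat(sprintf("  RMS residual = %.3g um/s over %d points\n",
              x$residual, nrow(x$field$points)))
  invisible(x)
}

#' @rdname fit_stokeslet
#' @param object a `stokeslet_fit`.
#' @param ... unused.
#' @export
coef.stokeslet_fit <- function(object, ...) {
  c(x0_x = object$x0[1], x0_y = object$x0[2],
    G_x = object$G[1], G_y = object$G[2])
}

#' @rdname fit_stokeslet
#' @param newpoints optional n x 2 matrix of evaluation points; defaults to
#'   the fitted field's grid.
#' @export
predict.stokeslet_fit <- function(object, newpoints = NULL, ...) {
  if (is.null(newpoints)) newpoints <- object$field$points
  evaluate_stokeslet(object$G, object$x0, newpoints)
}

#' @rdname fit_stokeslet
#' @export
residuals.stokeslet_fit <- function(object, ...) {
  object$field$u - predict(object)
}

#' Time-averaged flow field
#'
#' Per-point time averages over a sequence of congruent snapshots: the mean
#' speed `< |u| >_t` (the scalar average used for radial-decay analysis) and
#' the mean velocity vector (the average used for streamlines). The two
#' differ whenever the flow direction varies over the beat.
#'
#' @param frames list of [velocity_field] objects on identical grids.
#' @return A list with `points`, `mean_speed` (um/s), `mean_u` (n x 2,
#'   um/s) and `n_frames`.
#' @export
time_average_field <- function(frames) {
  stopifnot(length(frames) >= 1)
  p0 <- frames[[1]]$points
  speed <- 0; uacc <- 0
  for (f in frames) {
    if (!isTRUE(all.equal(f$points, p0, tolerance = 1e-10)))
      stop("frames are not on congruent grids")
    speed <- speed + sqrt(rowSums(f$u^2))
    uacc <- uacc + f$u
  }
  list(points = p0, mean_speed = speed / length(frames),
       mean_u = uacc / length(frames), n_frames = length(frames))
}

#' Radial decay of a scalar speed field
#'
#' Samples a scalar field along a ray from `origin` in direction
#' `direction` and fits a power law `u ~ r^p` by least squares in log-log
#' coordinates. A Stokeslet field gives exponent -1, a source dipole -2.
#' Samples are taken at the grid points nearest to equally spaced positions
#' along the ray (each sample uses the chosen point's true distance from
#' the origin, so exact model fields yield exact exponents).
#'
#' @param points n x 2 matrix of field sample locations (um).
#' @param speed scalar field values at `points` (um/s).
#' @param origin ray origin (um).
#' @param direction ray direction (need not be normalised).
#' @param r_min,r_max fit window along the ray (um).
#' @param n_samples number of sampling stations along the ray.
#' @return A list with `samples` (data frame `r`, `u`), `exponent`,
#'   `std_error` and the `lm` fit.
#' @export
radial_decay <- function(points, speed, origin, direction,
                         r_min, r_max, n_samples = 25) {
  dir <- direction / sqrt(sum(direction^2))
  targets <- seq(r_min, r_max, length.out = n_samples)
  idx <- integer(0)
  for (rt in targets) {
    pos <- origin + rt * dir
    d2 <- (points[, 1] - pos[1])^2 + (points[, 2] - pos[2])^2
    idx <- c(idx, which.min(d2))
  }
  idx <- unique(idx)
  r <- sqrt((points[idx, 1] - origin[1])^2 + (points[idx, 2] - origin[2])^2)
  keep <- r >= r_min * 0.99 & r <= r_max * 1.01 & speed[idx] > 0
  r <- r[keep]; u <- speed[idx][keep]
  if (length(r) < 5) stop("fewer than 5 usable samples in the fit window")
  fit <- stats::lm(log(u) ~ log(r))
  sm <- suppressWarnings(summary(fit))$coefficients
  list(samples = data.frame(r = r, u = u),
       exponent = unname(stats::coef(fit)[2]),
       std_error = unname(sm[2, 2]), fit = fit)
}

#' Fit sinusoidal force modulation over the beat
#'
#' Fits `|G|(t) = A0 (1 + A1 sin(2 pi t / T + phi0))` to a series of
#' per-frame fitted force magnitudes at a known beat period `T`. The model
#' is linear in `(A0, A0 A1 cos phi0, A0 A1 sin phi0)` and is solved
#' exactly; `A1` is reported non-negative with `phi0` adjusted accordingly.
#'
#' @param t sample times (s), spanning at least two full periods.
#' @param g force magnitudes `|F|/(8 pi mu)` (um^2/s).
#' @param period beat period `T` (s).
#' @return An object of class `force_modulation` with elements `A0`
#'   (um^2/s), `A1`, `period` (s), `phi0` (rad) and `residual`.
#' @export
fit_force_modulation <- function(t, g, period) {
  if (diff(range(t)) < period)
    stop("series shorter than one beat period")
  if (diff(range(t)) < 2 * period)
    warning("fewer than two full periods of samples")
  s <- sin(2 * pi * t / period); c2 <- cos(2 * pi * t / period)
  fit <- stats::lm(g ~ s + c2)
  cf <- stats::coef(fit)
  A0 <- unname(cf[1])
  b <- unname(cf[2]); cc <- unname(cf[3])
  A1 <- sqrt(b^2 + cc^2) / A0
  phi0 <- atan2(cc, b)
  structure(list(A0 = A0, A1 = A1, period = period, phi0 = phi0,
                 residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "force_modulation")
}

#' @export
print.force_modulation <- function(x, ...) {
  cat(sprintf(
    "Force modulation: |G|(t) = %.4g (1 + %.3f sin(2 pi t / %.4g + %.3f))\n",
    x$A0, x$A1, x$period, x$phi0))
  cat(sprintf("  RMS residual %.3g um^2/s\n", x$residual))
  invisible(x)
}

#' @rdname fit_force_modulation
#' @param object a `force_modulation`.
#' @param ... unused.
#' @export
coef.force_modulation <- function(object, ...) {
  c(A0 = object$A0, A1 = object$A1, period = object$period,
    phi0 = object$phi0)
}

#' @rdname fit_force_modulation
#' @param newtimes times at which to evaluate the fitted modulation (s).
#' @export
predict.force_modulation <- function(object, newtimes, ...) {
  object$A0 * (1 + object$A1 *
                 sin(2 * pi * newtimes / object$period + object$phi0))
}

#' Rotational-stiffness lower bound from interflagellar torque
#'
#' Estimates the hydrodynamic torque exerted on one flagellum by the flow of
#' a neighbouring cell, and converts an upper bound on the observed angular
#' displacement into a lower bound on the effective rotational spring
#' constant. The flow speed at distance `r` from a point force of reduced
#' magnitude `G` is `u = G / r`; acting along a flagellum of length `l` it
#' produces a torque of order `C_perp u l^2 / 2` (with the Lighthill normal
#' drag coefficient), and the bound is `k > torque / alpha_star`.
#'
#' @param l flagellum length (um).
#' @param r distance from the force to the flagellum (um).
#' @param G reduced force magnitude `F/(8 pi mu)` (um^2/s).
#' @param alpha_star upper bound on the angular displacement (rad).
#' @param aspect_ratio slenderness ratio for the Lighthill coefficient.
#' @param mu dynamic viscosity (Pa s).
#' @return A list with `u` (um/s), `torque` (pN um) and `k_bound` (pN um),
#'   using the unit identity 1 Pa s x um^3 / s = 1 pN um.
#' @export
rotational_stiffness_bound <- function(l, r, G, alpha_star,
                                       aspect_ratio = 80, mu = 1e-3) {
  stopifnot(l > 0, r > 0, G > 0, aspect_ratio > 0)
  if (alpha_star <= 0) stop("alpha_star must be positive: bound undefined")
  cf <- lighthill_coefficients(mu, aspect_ratio)
  u <- G / r
  torque <- cf$C_perp * u * l^2 / 2   # Pa s * um/s * um^2 = pN um
  list(u = u, torque = torque, k_bound = torque / alpha_star)
}
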