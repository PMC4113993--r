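# Independent oracles and small fixture builders used across the suite.

# Brute-force Stokeslet fit: exhaustive grid search over x0 with an exact
# linear solve for G, written directly from the point-force kernel
# u = G/r + (rhat.G) rhat / r (independent of the package's fit path).
oracle_grid_search <- function(field, x_range, y_range, n = 21) {
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)
  b <- c(field$u[, 1], field$u[, 2])
  best <- list(rss = Inf)
  for (x in xs) for (y in ys) {
    rx <- field$points[, 1] - x
    ry <- field$points[, 2] - y
    r2 <- rx^2 + ry^2
    if (any(r2 < 1e-12)) next
    r <- sqrt(r2)
    # columns: response to G = (1, 0) and G = (0, 1)
    c1 <- c((1 + rx * rx / r2) / r, (ry * rx / r2) / r)
    c2 <- c((rx * ry / r2) / r, (1 + ry * ry / r2) / r)
    fit <- stats::lm.fit(cbind(c1, c2), b)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, x0 = c(x, y), G = unname(fit$coefficients))
  }
  best
}

# Stokeslet field snapshot on a square grid with a disc excluded around x0.
make_stokeslet_field <- function(G, x0, extent = 50, spacing = 5,
                                 exclude = 5, noise_sd = 0) {
  g <- seq(-extent, extent, by = spacing)
  pts <- as.matrix(expand.grid(g, g))
  pts <- pts[(pts[, 1] - x0[1])^2 + (pts[, 2] - x0[2])^2 > exclude^2, ]
  u <- evaluate_stokeslet(G, x0, pts)
  if (noise_sd > 0) u <- u + matrix(rnorm(length(u), sd = noise_sd), ncol = 2)
  velocity_field(pts[, 1], pts[, 2], u[, 1], u[, 2])
}

# Discrete AR(1) realisation of an Ornstein-Uhlenbeck process with
# relaxation rate r and diffusion D (independent of the C++ integrator).
oracle_ou <- function(n, r, D, dt, x0 = 0) {
  x <- numeric(n)
  x[1] <- x0
  noise <- rnorm(n - 1, sd = sqrt(2 * D * dt))
  for (i in 2:n) x[i] <- x[i - 1] * (1 - r * dt) + noise[i - 1]
  x
}

# Direct slip counter on a raw Delta series: counts well-to-well
# transitions with hysteresis (a transition registers only when Delta has
# moved at least 0.75 beats from the current well centre).
oracle_count_slips <- function(delta) {
  well <- round(delta[1])
  slips <- 0
  for (d in delta) {
    if (abs(d - well) >= 0.75) {
      well <- round(d)
      slips <- slips + 1
    }
  }
  slips
}

# Phase pair built directly from a Delta series (beats) on a uniform grid,
# bypassing the generators.
make_pair <- function(t, delta, omega_bar = 33, L = 1,
                      orientation = "IP") {
  common <- 2 * pi * omega_bar * t
  structure(list(t = t, delta = delta,
                 phi1 = common + pi * delta, phi2 = common - pi * delta,
                 dt = t[2] - t[1], d = L * 19.9, l = 19.9, L = L,
                 orientation = orientation, ground_truth = NULL),
            class = "phase_pair")
}
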