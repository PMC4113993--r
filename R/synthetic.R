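#' Configuration for the synthetic-data generators
#'
#' Bundles the acquisition settings shared by all synthetic-data
#' generators. A fixed seed makes every generator's output reproducible.
#'
#' @param seed integer seed for all randomness in the generators.
#' @param frame_rate sampling rate (frames per second); the default 1000
#'   matches high-speed imaging of flagellar beats.
#' @param duration generated time span (s).
#' @param noise_piv fractional amplitude (relative to the per-frame RMS
#'   speed) of the additive Gaussian velocity noise.
#' @param noise_signal fractional amplitude (relative to the signal
#'   amplitude) of the additive noise on interrogation signals.
#' @param grid_extent half-width of the square velocity grid (um).
#' @param grid_spacing grid spacing (um).
#' @param near_field_cutoff radius (um) of the disc around the point-force
#'   trajectory excluded from velocity grids; the Stokeslet description
#'   only holds in the far field, and the cutoff also guards the 1/r
#'   singularity.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, frame_rate = 1000, duration = 1,
                             noise_piv = 0, noise_signal = 0,
                             grid_extent = 50, grid_spacing = 2.5,
                             near_field_cutoff = 5) {
  stopifnot(frame_rate > 0, duration > 0, noise_piv >= 0, noise_signal >= 0,
            grid_extent > 0, grid_spacing > 0, near_field_cutoff >= 0)
  seed <- as.integer(seed)
  stopifnot(is.finite(seed), abs(seed) < 2^31 - 16)
  structure(list(seed = seed, frame_rate = frame_rate, duration = duration,
                 noise_piv = noise_piv, noise_signal = noise_signal,
                 grid_extent = grid_extent, grid_spacing = grid_spacing,
                 near_field_cutoff = near_field_cutoff),
            class = "synthetic_config")
}

#' Generate synthetic PIV-like velocity snapshots
#'
#' Emulates a movie of gridded velocity snapshots produced by a beating
#' flagellum: a point force moves along a closed trajectory with
#' sinusoidally modulated magnitude, and every frame is the exact
#' Stokeslet field of the instantaneous `(x0, G)` plus independent
#' zero-mean Gaussian velocity noise. The grid excludes a disc of radius
#' `config$near_field_cutoff` around the trajectory.
#'
#' @param config a [synthetic_config].
#' @param trajectory function of time returning the point-force position
#'   (length-2, um); must be periodic with the modulation period.
#' @param force_profile list with `A0` (um^2/s), `A1` (in `[0, 1)`),
#'   `period` (s), `phi0` (rad) and `direction` (fixed length-2 vector or
#'   a function of time), describing the reduced force
#'   `G(t) = A0 (1 + A1 sin(2 pi t / period + phi0)) * direction(t)`.
#' @return A list of [velocity_field] frames with attribute
#'   `ground_truth`: a list with the per-frame `t`, `x0` and `G` plus the
#'   generating parameters.
#' @export
generate_piv_frames <- function(config, trajectory, force_profile) {
  stopifnot(inherits(config, "synthetic_config"))
  fp <- force_profile
  stopifnot(fp$A0 > 0, fp$A1 >= 0, fp$A1 < 1, fp$period > 0)
  if (is.null(fp$phi0)) fp$phi0 <- 0
  dirfun <- if (is.function(fp$direction)) fp$direction else {
    v <- fp$direction / sqrt(sum(fp$direction^2))
    function(t) v
  }
  g <- seq(-config$grid_extent, config$grid_extent, by = config$grid_spacing)
  pts <- as.matrix(expand.grid(x = g, y = g))
  path <- t(vapply(seq(0, fp$period, length.out = 129)[-129], trajectory,
                   numeric(2)))
  mind <- apply(pts, 1, function(p)
    sqrt(min((path[, 1] - p[1])^2 + (path[, 2] - p[2])^2)))
  pts <- pts[mind > config$near_field_cutoff, , drop = FALSE]
  if (nrow(pts) < 10) stop("near-field cutoff excluded almost the whole grid")
  times <- seq(0, config$duration, by = 1 / config$frame_rate)
  set.seed(config$seed + 1L)
  frames <- vector("list", length(times))
  x0s <- matrix(0, length(times), 2)
  Gs <- matrix(0, length(times), 2)
  for (i in seq_along(times)) {
    tt <- times[i]
    x0 <- trajectory(tt)
    G <- fp$A0 * (1 + fp$A1 * sin(2 * pi * tt / fp$period + fp$phi0)) *
      dirfun(tt)
    u <- evaluate_stokeslet(G, x0, pts)
    if (config$noise_piv > 0) {
      sdn <- config$noise_piv * sqrt(mean(rowSums(u^2)))
      u <- u + matrix(stats::rnorm(length(u), sd = sdn), ncol = 2)
    }
    frames[[i]] <- velocity_field(pts[, 1], pts[, 2], u[, 1], u[, 2], t = tt)
    x0s[i, ] <- x0
    Gs[i, ] <- G
  }
  attr(frames, "ground_truth") <- list(
    t = times, x0 = x0s, G = Gs,
    A0 = fp$A0, A1 = fp$A1, period = fp$period, phi0 = fp$phi0,
    noise_piv = config$noise_piv, seed = config$seed)
  frames
}

#' Generate inextensible beating-flagellum waveforms
#'
#' Builds planar flagellar polylines from a single-harmonic tangent-angle
#' travelling wave, `psi(s, t) = psi0(s) + A(s) sin(2 pi (s / Lambda -
#' t / period))`, and integrates `(cos psi, sin psi)` along arclength so
#' the filament is inextensible by construction. This is a stand-in for a
#' real power/recovery beat, not a fit to any measured waveform: the
#' distally growing amplitude produces the propulsive asymmetry the
#' analysis stages need, nothing more.
#'
#' @param config a [synthetic_config]; `frame_rate` and `duration` set the
#'   frame grid.
#' @param beat list with `l` (total length, um), `period` (s), `Lambda`
#'   (wavelength of the travelling wave, um), `amplitude` (max tangent
#'   angle, rad, reached at the distal tip; or a function of arclength),
#'   `psi0` (mean tangent angle, rad; or a function of arclength) and
#'   `n_nodes`.
#' @return A list of [waveform_frame] objects with attribute
#'   `ground_truth` (the beat parameters).
#' @export
generate_waveforms <- function(config,
                               beat = list(l = 19.9, period = 1 / 33,
                                           Lambda = 19.9, amplitude = 0.6,
                                           psi0 = 0.25, n_nodes = 1024)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(beat$n_nodes)) beat$n_nodes <- 1024
  if (beat$Lambda <= 0 || beat$period <= 0)
    stop("invalid beat model: Lambda and period must be positive")
  stopifnot(beat$l > 0, beat$n_nodes >= 8)
  ampfun <- if (is.function(beat$amplitude)) beat$amplitude else
    function(s) beat$amplitude * s / beat$l
  psi0fun <- if (is.function(beat$psi0)) beat$psi0 else
    function(s) rep(beat$psi0, length(s))
  oversample <- 4L
  nf <- oversample * (beat$n_nodes - 1L) + 1L
  sf <- seq(0, beat$l, length.out = nf)
  node_idx <- seq(1L, nf, by = oversample)
  times <- seq(0, config$duration, by = 1 / config$frame_rate)
  frames <- lapply(times, function(tt) {
    psi <- psi0fun(sf) + ampfun(sf) *
      sin(2 * pi * (sf / beat$Lambda - tt / beat$period))
    x <- cumtrapz(sf, cos(psi))
    y <- cumtrapz(sf, sin(psi))
    waveform_frame(cbind(x[node_idx], y[node_idx]), t = tt,
                   s = sf[node_idx])
  })
  attr(frames, "ground_truth") <- beat
  frames
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

#' Generate a coupled noisy phase-oscillator pair
#'
#' Integrates the stochastic Adler dynamics of the phase difference
#' `Delta(t)` (delegating to [simulate_adler()]) and splits it
#' symmetrically between two phases advancing at the common mean beat
#' frequency: `phi1 = 2 pi omega_bar t + pi Delta`,
#' `phi2 = 2 pi omega_bar t - pi Delta`. The common-mode phase is
#' irrelevant to every downstream statistic.
#'
#' @param config a [synthetic_config]; `frame_rate` sets the output
#'   sampling, `duration` the span.
#' @param params an [adler_params] triple.
#' @param omega_bar mean beat frequency (Hz), positive.
#' @param L scaled separation `d / l` carried as metadata.
#' @param delta0 initial phase difference (beats).
#' @param l mean flagellar length (um), metadata.
#' @param orientation `"IP"` or `"AP"` tag (default by sign of `eps`).
#' @param dt Euler-Maruyama step (s); must divide the frame interval.
#' @return A [phase_difference] object (class `phase_pair`) whose
#'   `ground_truth` element stores the generating parameters and the exact
#'   simulated `Delta(t)`.
#' @export
generate_pair_phases <- function(config, params, omega_bar, L,
                                 delta0 = 0, l = 19.9,
                                 orientation = NULL, dt = 1e-4) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "adler_params"))
  if (omega_bar <= 0) stop("omega_bar must be positive")
  stopifnot(L > 0)
  thin <- round(1 / (config$frame_rate * dt))
  stopifnot(thin >= 1)
  if (is.null(orientation))
    orientation <- if (params$eps >= 0) "IP" else "AP"
  sim <- simulate_adler(params, delta0 = delta0, dt = dt,
                        duration = config$duration,
                        seed = config$seed + 2L, thin = thin)
  tt <- sim$t
  common <- 2 * pi * omega_bar * tt
  pair <- structure(list(
    t = tt, delta = sim$delta,
    phi1 = common + pi * sim$delta, phi2 = common - pi * sim$delta,
    dt = sim$dt, d = L * l, l = l, L = L, orientation = orientation,
    ground_truth = list(params = params, omega_bar = omega_bar,
                        delta0 = delta0, L = L, delta = sim$delta,
                        seed = config$seed)),
    class = "phase_pair")
  pair
}

#' Generate interrogation-region signals from a phase pair
#'
#' Maps each oscillator phase through a periodic scalar waveshape to
#' emulate the intensity signal of a video interrogation region, adding
#' optional white noise. The waveshape must cross its section level
#' upwards exactly once per period, so that Poincare sectioning of the
#' output recovers the input phases beat for beat.
#'
#' @param config a [synthetic_config]; `noise_signal` sets the noise
#'   fraction.
#' @param pair a `phase_pair`.
#' @param waveshape periodic scalar function on `[0, 2 pi)`; default
#'   [sin()].
#' @return A list with `t`, `s1`, `s2` (the two signals) and attribute
#'   `ground_truth` (the pair's generating record).
#' @export
generate_section_signal <- function(config, pair, waveshape = sin) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pair, "phase_pair"))
  probe <- waveshape(seq(0, 2 * pi, length.out = 2049)[-2049])
  lvl <- mean(range(probe))
  up <- sum(probe[-length(probe)] <= lvl & probe[-1] > lvl) +
    (probe[length(probe)] <= lvl && probe[1] > lvl)
  if (up != 1)
    stop("waveshape must cross its section level upwards exactly once per period")
  set.seed(config$seed + 3L)
  amp <- diff(range(probe)) / 2
  mk <- function(phi) {
    s <- waveshape(phi %% (2 * pi))
    if (config$noise_signal > 0)
      s <- s + stats::rnorm(length(s), sd = config$noise_signal * amp)
    s
  }
  out <- list(t = pair$t, s1 = mk(pair$phi1), s2 = mk(pair$phi2),
              section_level = lvl)
  attr(out, "ground_truth") <- pair$ground_truth
  out
}
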