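#' Phase extraction by Poincare sectioning
#'
#' Reconstructs a continuous beat phase from a scalar oscillatory signal by
#' detecting its threshold crossings in a fixed direction (the Poincare
#' section), so that the oscillator passes the section exactly once per
#' beat. Crossing times are refined by linear sub-sample interpolation and
#' the phase `phi(t)` is piecewise linear, gaining `2 pi` between
#' consecutive crossings. Two guards enforce the once-per-beat rule on
#' noisy signals: a hysteresis band (the signal must retreat below the
#' threshold by `hysteresis` times the signal amplitude before the next
#' crossing is armed) and a refractory window (default: half the median
#' beat period, estimated from an initial pass).
#'
#' @param t sample times (s), uniformly spaced.
#' @param x signal values.
#' @param threshold section level.
#' @param direction `"up"` (default) or `"down"` crossings.
#' @param refractory refractory window (s), or `NULL` for the automatic
#'   half-median-period rule.
#' @param hysteresis re-arming depth as a fraction of the signal
#'   amplitude (the amplitude is taken as half the central 95 percent
#'   range).
#' @return An object of class `phase_series`: list with `crossings`
#'   (section passage times, s), `t` (sampling times within the phase
#'   support), `phi` (rad, non-decreasing) and `dt`.
#' @export
poincare_phase <- function(t, x, threshold = 0, direction = c("up", "down"),
                           refractory = NULL, hysteresis = 0.25) {
  direction <- match.arg(direction)
  if (direction == "down") x <- -x + 2 * threshold
  n <- length(x)
  stopifnot(length(t) == n, n >= 3)
  amp <- diff(stats::quantile(x, c(0.025, 0.975), names = FALSE)) / 2
  arm_level <- threshold - hysteresis * amp
  up <- which(x[-n] <= threshold & x[-1] > threshold)
  if (length(up) < 3) stop("signal crosses the section fewer than 3 times")
  # a crossing counts only if the signal has dipped below the arming
  # level since the previous accepted crossing (the start counts as armed)
  ca <- cumsum(x < arm_level)
  idx <- integer(0)
  prev <- 0L
  for (k in up) {
    if (prev == 0L || ca[k] - ca[prev] > 0) {
      idx <- c(idx, k)
      prev <- k
    }
  }
  if (length(idx) < 3) stop("signal crosses the section fewer than 3 times")
  frac <- (threshold - x[idx]) / (x[idx + 1] - x[idx])
  tc <- t[idx] + frac * (t[idx + 1] - t[idx])
  if (is.null(refractory)) refractory <- stats::median(diff(tc)) / 2
  keep <- c(TRUE, rep(FALSE, length(tc) - 1))
  last <- tc[1]
  for (i in seq_along(tc)[-1]) {
    if (tc[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tc[i]
    }
  }
  tc <- tc[keep]
  if (length(tc) < 3) stop("fewer than 3 crossings after refractory filtering")
  support <- t >= tc[1] & t <= tc[length(tc)]
  ts <- t[support]
  phi <- stats::approx(tc, 2 * pi * (seq_along(tc) - 1), xout = ts)$y
  structure(list(crossings = tc, t = ts, phi = phi,
                 dt = stats::median(diff(t))),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  nb <- length(x$crossings) - 1
  cat(sprintf("Phase series: %d beats over %.3g s (mean frequency %.3f Hz)\n",
              nb, diff(range(x$crossings)),
              nb / diff(range(x$crossings))))
  invisible(x)
}

#' Phase-difference series for a flagellar pair
#'
#' Forms the unwrapped phase difference `Delta(t) = (phi1 - phi2) / (2 pi)`
#' (in beats) of two phase series on their common time support, resampled
#' to a uniform grid.
#'
#' @param p1,p2 [poincare_phase] results (or any list with `t`, `phi`).
#' @param d interflagellar separation (um), optional metadata.
#' @param l mean flagellar length (um), optional metadata.
#' @param orientation `"IP"` or `"AP"` configuration tag.
#' @return An object of class `phase_pair`: list with `t`, `delta` (beats,
#'   unwrapped), `phi1`, `phi2` (rad), `dt`, `d`, `l`, `L = d/l` and
#'   `orientation`.
#' @export
phase_difference <- function(p1, p2, d = NA_real_, l = NA_real_,
                             orientation = NA_character_) {
  t0 <- max(min(p1$t), min(p2$t))
  t1 <- min(max(p1$t), max(p2$t))
  if (t0 >= t1) stop("phase series have disjoint time supports")
  dt <- min(stats::median(diff(p1$t)), stats::median(diff(p2$t)))
  tt <- seq(t0, t1, by = dt)
  phi1 <- stats::approx(p1$t, p1$phi, xout = tt)$y
  phi2 <- stats::approx(p2$t, p2$phi, xout = tt)$y
  structure(list(t = tt, delta = (phi1 - phi2) / (2 * pi),
                 phi1 = phi1, phi2 = phi2, dt = dt,
                 d = d, l = l, L = d / l, orientation = orientation,
                 ground_truth = NULL),
            class = "phase_pair")
}

#' @export
print.phase_pair <- function(x, ...) {
  cat(sprintf("Phase pair: %d samples over %.3g s, Delta %.3f -> %.3f beats\n",
              length(x$t), diff(range(x$t)), x$delta[1],
              x$delta[length(x$delta)]))
  if (is.finite(x$L))
    cat(sprintf("  L = %.3g (d = %.3g um, l = %.3g um), orientation %s\n",
                x$L, x$d, x$l, x$orientation))
  invisible(x)
}

#' Detect phase-locked segments and slips
#'
#' Segments a phase-difference series into phase-locked stretches and
#' phase slips. The integer winding number `n(t) = round(Delta - Delta_ref)`
#' (with `Delta_ref` the circular mean of the fractional part of `Delta`)
#' is piecewise constant while the pair is locked; a slip is a change of
#' `n` sustained for at least `hold` seconds. Maximal constant-`n`
#' intervals of duration >= `hold` are the locked segments; excursions that
#' re-trap within `hold` are not counted as slips.
#'
#' @param pair a [phase_difference] series, uniformly sampled.
#' @param hold minimum sustained duration (s) for a segment; default is 3
#'   mean beat periods (or 3 mean sampling intervals if the beat rate is
#'   unavailable).
#' @return An object of class `locked_stats`: list with `segments` (data
#'   frame `start`, `end`, `start_index`, `end_index`, `n`, `duration`),
#'   `slips` (data frame `time`, `sign`), `Delta0` (mean of `Delta - n`
#'   over locked samples), `variance` (of the locked fluctuations),
#'   `tau_sync` (mean segment duration, s), `winding` (per-sample `n`),
#'   `locked` (logical per sample) and `locked_fraction`.
#' @export
detect_locked <- function(pair, hold = NULL) {
  stopifnot(inherits(pair, "phase_pair"))
  delta <- pair$delta
  tt <- pair$t
  dt <- pair$dt
  if (is.null(hold)) {
    fr <- try(beat_frequencies(pair), silent = TRUE)
    hold <- if (!inherits(fr, "try-error") && is.finite(fr$omega_bar) &&
                fr$omega_bar > 0) 3 / fr$omega_bar else 3 * dt
  }
  if (diff(range(tt)) < hold) stop("series shorter than the hold time")
  frac <- delta - floor(delta)
  ref <- atan2(mean(sin(2 * pi * frac)), mean(cos(2 * pi * frac))) / (2 * pi)
  n <- round(delta - ref)
  r <- rle(n)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  durations <- tt[ends] - tt[starts] + dt
  is_seg <- durations >= hold
  segs <- data.frame(start = tt[starts[is_seg]], end = tt[ends[is_seg]],
                     start_index = starts[is_seg], end_index = ends[is_seg],
                     n = r$values[is_seg], duration = durations[is_seg])
  slips <- data.frame(time = numeric(0), sign = integer(0))
  if (nrow(segs) > 1) {
    dn <- diff(segs$n)
    nonzero <- which(dn != 0)
    if (length(nonzero)) {
      times <- (segs$end[nonzero] + segs$start[nonzero + 1]) / 2
      slips <- data.frame(
        time = rep(times, abs(dn[nonzero])),
        sign = rep(sign(dn[nonzero]), abs(dn[nonzero])))
      slips <- slips[order(slips$time), , drop = FALSE]
    }
  }
  locked <- rep(FALSE, length(delta))
  for (i in seq_len(nrow(segs)))
    locked[segs$start_index[i]:segs$end_index[i]] <- TRUE
  dev <- delta[locked] - n[locked]
  Delta0 <- if (length(dev)) mean(dev) else NA_real_
  structure(list(segments = segs, slips = slips, Delta0 = Delta0,
                 variance = if (length(dev) > 1) stats::var(dev) else NA_real_,
                 tau_sync = if (nrow(segs)) mean(segs$duration) else NA_real_,
                 winding = n, locked = locked,
                 locked_fraction = mean(locked), hold = hold),
            class = "locked_stats")
}

#' @export
print.locked_stats <- function(x, ...) {
  cat(sprintf("Locked-state statistics: %d segments, %d slips\n",
              nrow(x$segments), nrow(x$slips)))
  cat(sprintf("  Delta0 = %.3f beats, variance %.4g, tau_sync = %.3g s, locked fraction %.2f\n",
              x$Delta0, x$variance, x$tau_sync, x$locked_fraction))
  invisible(x)
}

#' Fluctuation statistics of the locked phase difference
#'
#' Distribution of the locked-state fluctuations `Delta - Delta0`, rescaled
#' by `sqrt(L)` so that series at different separations collapse when the
#' coupling scales as `1/L`. Fits a Gaussian by maximum likelihood and
#' reports a Kolmogorov-Smirnov normality diagnostic.
#'
#' @param pair the [phase_difference] series.
#' @param stats_locked the matching [detect_locked()] result (computed if
#'   missing).
#' @param L scaled separation used for rescaling; defaults to `pair$L`.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return An object of class `fluctuation_stats`: list with `rescaled`
#'   (the `(Delta - Delta0)/sqrt(L)` samples), `mu`, `sigma` (Gaussian
#'   MLE), `C0` (unrescaled fluctuation variance), `ks_stat`, and
#'   `density` (histogram of the rescaled samples).
#' @export
fluctuation_stats <- function(pair, stats_locked = NULL, L = NULL,
                              breaks = 50) {
  if (is.null(stats_locked)) stats_locked <- detect_locked(pair)
  if (is.null(L)) L <- pair$L
  stopifnot(is.finite(L), L > 0)
  dev <- (pair$delta - stats_locked$winding)[stats_locked$locked] -
    stats_locked$Delta0
  if (length(dev) < 100) stop("fewer than 100 locked samples")
  resc <- dev / sqrt(L)
  mu <- mean(resc)
  sigma <- sqrt(mean((resc - mu)^2))
  ks_stat <- if (sigma > 0)
    unname(suppressWarnings(stats::ks.test(resc, "pnorm", mu,
                                           sigma))$statistic)
  else NA_real_
  h <- graphics::hist(resc, breaks = breaks, plot = FALSE)
  structure(list(rescaled = resc, mu = mu, sigma = sigma,
                 C0 = stats::var(dev), ks_stat = ks_stat,
                 density = h),
            class = "fluctuation_stats")
}

#' @export
print.fluctuation_stats <- function(x, ...) {
  cat(sprintf(
    "Locked fluctuations: n = %d, Gaussian fit sigma = %.4g (rescaled), C0 = %.4g beats^2\n",
    length(x$rescaled), x$sigma, x$C0))
  cat(sprintf("  KS normality statistic %.4g\n", x$ks_stat))
  invisible(x)
}

#' Beat frequencies and frequency difference of a pair
#'
#' Mean beat frequencies `omega_i = (beat count) / (elapsed time)` of the
#' two flagella, their difference `delta_omega = omega_1 - omega_2`, and,
#' if a far-separation reference is supplied, the normalised difference
#' `delta_omega / delta_omega_far`. Note that a locked pair has
#' `delta_omega = 0` even though the intrinsic difference `delta_nu` is
#' non-zero.
#'
#' @param pair a [phase_difference] series.
#' @param delta_omega_far optional far-separation frequency difference
#'   (Hz).
#' @return A list with `omega1`, `omega2`, `omega_bar`, `delta_omega`
#'   (Hz) and `ratio` (`delta_omega / delta_omega_far`, or `NA`).
#' @export
beat_frequencies <- function(pair, delta_omega_far = NULL) {
  span <- pair$t[length(pair$t)] - pair$t[1]
  n1 <- (pair$phi1[length(pair$phi1)] - pair$phi1[1]) / (2 * pi)
  n2 <- (pair$phi2[length(pair$phi2)] - pair$phi2[1]) / (2 * pi)
  if (min(n1, n2) < 10) stop("fewer than 10 beats in the series")
  omega1 <- n1 / span
  omega2 <- n2 / span
  list(omega1 = omega1, omega2 = omega2,
       omega_bar = (omega1 + omega2) / 2,
       delta_omega = omega1 - omega2,
       ratio = if (is.null(delta_omega_far)) NA_real_ else
         (omega1 - omega2) / delta_omega_far)
}
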