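#' Lighthill resistive-force drag coefficients
#'
#' Normal and tangential drag coefficients for a slender filament,
#' `C_perp = 4 pi mu / (ln(0.18 L/a) + 1/2)` and
#' `C_par  = 2 pi mu / (ln(0.18 L/a) - 1/2)`,
#' where `L/a` is the wavelength-to-radius aspect ratio. The tangential
#' coefficient diverges as the aspect ratio approaches `exp(1/2)/0.18`
#' from above, so smaller values are rejected. The ratio `C_perp/C_par`
#' increases monotonically towards 2 for very slender filaments.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param aspect_ratio wavelength-to-radius ratio (dimensionless).
#' @return A list of class `drag_coefficients` with `C_perp`, `C_par`
#'   (Pa s) and `aspect_ratio`.
#' @export
lighthill_coefficients <- function(mu = 1e-3, aspect_ratio = 80) {
  stopifnot(mu > 0)
  if (aspect_ratio <= exp(0.5) / 0.18)
    stop("aspect ratio at or below the C_par singularity (exp(1/2)/0.18)")
  lg <- log(0.18 * aspect_ratio)
  structure(list(C_perp = 4 * pi * mu / (lg + 0.5),
                 C_par = 2 * pi * mu / (lg - 0.5),
                 aspect_ratio = aspect_ratio),
            class = "drag_coefficients")
}

#' @export
print.drag_coefficients <- function(x, ...) {
  cat(sprintf(
    "Lighthill drag coefficients (aspect ratio %g):\n  C_perp = %.4g Pa s, C_par = %.4g Pa s, ratio %.3f\n",
    x$aspect_ratio, x$C_perp, x$C_par, x$C_perp / x$C_par))
  invisible(x)
}

#' Flagellar waveform frame
#'
#' An ordered planar polyline describing the tracked flagellum at one
#' instant, basal end first, with its cumulative arclength.
#'
#' @param nodes n x 2 matrix of node positions (um), basal end first.
#' @param t time stamp (s).
#' @param s optional arclength of each node (um); defaults to the
#'   cumulative chord length of the polyline.
#' @return An object of class `waveform_frame`.
#' @export
waveform_frame <- function(nodes, t = NA_real_, s = NULL) {
  nodes <- rbind(nodes)
  if (nrow(nodes) < 3) stop("a waveform frame needs at least 3 nodes")
  seg <- sqrt(rowSums(diff(nodes)^2))
  if (any(seg == 0)) stop("self-coincident consecutive nodes")
  if (is.null(s)) s <- c(0, cumsum(seg))
  if (any(diff(s) <= 0)) stop("arclength must be strictly increasing")
  structure(list(nodes = nodes, t = t, s = s), class = "waveform_frame")
}

#' @export
print.waveform_frame <- function(x, ...) {
  cat(sprintf("Waveform frame: %d nodes, arclength %.3f um", nrow(x$nodes),
              x$s[length(x$s)]))
  if (is.finite(x$t)) cat(sprintf(", t = %g s", x$t))
  cat("\n")
  invisible(x)
}

#' Node velocities by finite differences
#'
#' Velocities of corresponding nodes across a sequence of uniformly spaced
#' waveform frames: central differences in the interior, one-sided at the
#' first and last frame. Nodes correspond by index.
#'
#' @param frames list of [waveform_frame] objects with equal node counts
#'   and uniform time spacing.
#' @return A list of n x 2 velocity matrices (um/s), one per frame.
#' @export
node_velocities <- function(frames) {
  nf <- length(frames)
  if (nf < 3) stop("need at least 3 frames")
  nn <- vapply(frames, function(f) nrow(f$nodes), integer(1))
  if (length(unique(nn)) != 1) stop("frame node counts differ")
  tt <- vapply(frames, function(f) f$t, numeric(1))
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("frame interval not uniform")
  dt <- dt[1]
  lapply(seq_len(nf), function(i) {
    if (i == 1) (frames[[2]]$nodes - frames[[1]]$nodes) / dt
    else if (i == nf) (frames[[nf]]$nodes - frames[[nf - 1]]$nodes) / dt
    else (frames[[i + 1]]$nodes - frames[[i - 1]]$nodes) / (2 * dt)
  })
}

# Unit tangents at the nodes of a frame: centered differences in the
# interior, one-sided at the ends.
frame_tangents <- function(frame) {
  p <- frame$nodes
  n <- nrow(p)
  tg <- rbind(p[2, ] - p[1, ],
              p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
              p[n, ] - p[n - 1, ])
  len <- sqrt(rowSums(tg^2))
  if (any(len == 0)) stop("degenerate tangent (zero-length segment)")
  tg / len
}

#' Resistive-force-theory force density along a waveform
#'
#' Splits each node velocity into components normal and tangential to the
#' local filament tangent and assembles the local drag force density
#' `f = C_perp u_perp + C_par u_par`. With velocities in um/s and
#' coefficients in Pa s the densities are in pN/um directly
#' (1 Pa s x um/s = 1 pN/um).
#'
#' @param frame a [waveform_frame].
#' @param velocities n x 2 matrix of node velocities (um/s).
#' @param coeffs a [lighthill_coefficients] object.
#' @return An object of class `rft_record` with the per-node force density
#'   `f` (n x 2, pN/um), its normal/tangential magnitudes `f_perp`,
#'   `f_par` (signed, pN/um), the tangents, and the originating frame.
#' @export
rft_force_density <- function(frame, velocities, coeffs) {
  stopifnot(inherits(frame, "waveform_frame"),
            inherits(coeffs, "drag_coefficients"))
  tg <- frame_tangents(frame)
  upar_mag <- rowSums(velocities * tg)
  upar <- upar_mag * tg
  uperp <- velocities - upar
  f <- coeffs$C_perp * uperp + coeffs$C_par * upar
  nrm <- cbind(-tg[, 2], tg[, 1])
  structure(list(frame = frame, f = f,
                 f_perp = coeffs$C_perp * rowSums(uperp * nrm),
                 f_par = coeffs$C_par * upar_mag,
                 tangents = tg, coeffs = coeffs),
            class = "rft_record")
}

#' @export
print.rft_record <- function(x, ...) {
  F <- integrate_force(x)
  cat(sprintf(
    "RFT force record: %d nodes, |F| = %.4g pN (%.4g, %.4g)\n",
    nrow(x$f), sqrt(sum(F$F^2)), F$F[1], F$F[2]))
  invisible(x)
}

#' Integrated flagellar force
#'
#' Trapezoidal quadrature of the force density over arclength, giving the
#' total instantaneous force `F(t) = int_0^l f(s, t) ds`, together with the
#' signed normal and tangential component profiles along the filament.
#'
#' @param record an [rft_force_density] result.
#' @return A list with `F` (length-2 vector, pN; also `F_reduced` =
#'   `F/(8 pi mu)` in um^2/s) and `profiles` (data frame `s`, `f_normal`,
#'   `f_tangential` in pN/um).
#' @export
integrate_force <- function(record) {
  s <- record$frame$s
  f <- record$f
  w <- trapz_weights(s)
  Fv <- c(sum(w * f[, 1]), sum(w * f[, 2]))
  mu <- record$coeffs$C_perp * (log(0.18 * record$coeffs$aspect_ratio) + 0.5) /
    (4 * pi)
  list(F = Fv, F_reduced = Fv / (8 * pi * mu),
       profiles = data.frame(s = s, f_normal = record$f_perp,
                             f_tangential = record$f_par))
}

trapz_weights <- function(s) {
  n <- length(s)
  w <- numeric(n)
  ds <- diff(s)
  w[1] <- ds[1] / 2
  w[n] <- ds[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (ds[-(n - 1)] + ds[-1]) / 2
  w
}

#' Force-weighted centre of mass
#'
#' Effective centre of mass of the flagellum, weighting each node position
#' by the magnitude of its local force density:
#' `x = sum_i |f_i| x_i / sum_i |f_i|`. Used to build a limit-cycle
#' representation of the cyclic force variation.
#'
#' @param record an [rft_force_density] result.
#' @return Length-2 position (um).
#' @export
force_weighted_com <- function(record) {
  w <- sqrt(rowSums(record$f^2))
  if (all(w == 0)) stop("all force densities are zero: centre of mass undefined")
  colSums(record$frame$nodes * w) / sum(w)
}

#' Waveform angles at three stations
#'
#' Signed angles between the local filament tangent and the cell-body axis,
#' evaluated at arclength fractions 1/6 (proximal), 1/2 (mid) and 5/6
#' (distal). Tangent directions are interpolated between nodes.
#'
#' @param frame a [waveform_frame].
#' @param body_axis unit vector of the cell body axis.
#' @param fractions arclength fractions of the three stations.
#' @return Named numeric vector `x_a`, `x_b`, `x_c` (rad, in (-pi, pi]).
#' @export
waveform_angles <- function(frame, body_axis = c(1, 0),
                            fractions = c(1 / 6, 1 / 2, 5 / 6)) {
  ax <- body_axis / sqrt(sum(body_axis^2))
  tg <- frame_tangents(frame)
  s <- frame$s
  l <- s[length(s)]
  ang <- vapply(fractions, function(fr) {
    st <- fr * l
    i <- findInterval(st, s, all.inside = TRUE)
    w <- (st - s[i]) / (s[i + 1] - s[i])
    v <- (1 - w) * tg[i, ] + w * tg[i + 1, ]
    v <- v / sqrt(sum(v^2))
    atan2(ax[1] * v[2] - ax[2] * v[1], sum(ax * v))
  }, numeric(1))
  names(ang) <- c("x_a", "x_b", "x_c")
  ang
}
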