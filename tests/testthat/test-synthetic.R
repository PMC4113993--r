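test_that("generators are deterministic given the configuration", {
  cfg <- synthetic_config(seed = 13, duration = 0.05, noise_piv = 0.05,
                          noise_signal = 0.05, grid_extent = 30,
                          grid_spacing = 5)
  traj <- function(t) c(2 * cos(2 * pi * 33 * t), 8 + 2 * sin(2 * pi * 33 * t))
  prof <- list(A0 = 1000, A1 = 0.5, period = 1 / 33, phi0 = 0,
               direction = c(0, -1))
  f1 <- generate_piv_frames(cfg, traj, prof)
  f2 <- generate_piv_frames(cfg, traj, prof)
  expect_identical(f1, f2)
  w1 <- generate_waveforms(cfg)
  w2 <- generate_waveforms(cfg)
  expect_identical(w1, w2)
  par <- adler_params(0.5, 1, 0.1, 33)
  p1 <- generate_pair_phases(cfg, par, 33, L = 1)
  p2 <- generate_pair_phases(cfg, par, 33, L = 1)
  expect_identical(p1$delta, p2$delta)
  s1 <- generate_section_signal(cfg, p1)
  s2 <- generate_section_signal(cfg, p1)
  expect_identical(s1, s2)
})

test_that("noise-free static point force reproduces the exact Stokeslet", {
  cfg <- synthetic_config(seed = 1, duration = 3e-3, noise_piv = 0,
                          grid_extent = 30, grid_spacing = 5)
  frames <- generate_piv_frames(cfg, function(t) c(1, 2),
                                list(A0 = 900, A1 = 0, period = 1 / 33,
                                     phi0 = 0, direction = c(0.6, 0.8)))
  expect_gte(length(frames), 3)
  exact <- evaluate_stokeslet(900 * c(0.6, 0.8), c(1, 2),
                              frames[[1]]$points)
  for (f in frames) expect_equal(f$u, exact, ignore_attr = TRUE)
  # ground truth travels with the data
  gt <- attr(frames, "ground_truth")
  expect_equal(gt$A0, 900)
  expect_equal(gt$x0[1, ], c(1, 2))
  # the near-field cutoff keeps every grid point clear of the force
  d2 <- (frames[[1]]$points[, 1] - 1)^2 + (frames[[1]]$points[, 2] - 2)^2
  expect_gt(min(sqrt(d2)), cfg$near_field_cutoff)
})

test_that("velocity noise has the nominal fractional amplitude", {
  sds <- vapply(1:20, function(s) {
    cfg <- synthetic_config(seed = s, duration = 1e-4, noise_piv = 0.05,
                            grid_extent = 50, grid_spacing = 1)
    traj <- function(t) c(0, 0)
    prof <- list(A0 = 1000, A1 = 0, period = 1 / 33, phi0 = 0,
                 direction = c(0, 1))
    noisy <- generate_piv_frames(cfg, traj, prof)[[1]]
    exact <- evaluate_stokeslet(c(0, 1000), c(0, 0), noisy$points)
    stats::sd(noisy$u - exact)
  }, numeric(1))
  cfg0 <- synthetic_config(seed = 1, duration = 1e-4, noise_piv = 0,
                           grid_extent = 50, grid_spacing = 1)
  clean <- generate_piv_frames(cfg0, function(t) c(0, 0),
                               list(A0 = 1000, A1 = 0, period = 1 / 33,
                                    phi0 = 0, direction = c(0, 1)))[[1]]
  nominal <- 0.05 * sqrt(mean(rowSums(clean$u^2)))
  expect_equal(mean(sds), nominal, tolerance = 0.1)
})

test_that("generated waveforms are inextensible and periodic", {
  cfg <- synthetic_config(seed = 2, duration = 1 / 33)
  frames <- generate_waveforms(cfg)
  l <- attr(frames, "ground_truth")$l
  for (f in frames[seq(1, length(frames), by = 6)]) {
    chord <- sum(sqrt(rowSums(diff(f$nodes)^2)))
    expect_equal(chord, l, tolerance = 1e-6)
    expect_equal(f$s[length(f$s)], l)
  }
  # periodicity: a frame one full period later is identical
  cfg2 <- synthetic_config(seed = 2, duration = 2 / 33)
  frames2 <- generate_waveforms(cfg2, beat = list(l = 19.9, period = 0.01,
                                                  Lambda = 19.9,
                                                  amplitude = 0.6,
                                                  psi0 = 0.25,
                                                  n_nodes = 256))
  expect_equal(frames2[[1]]$nodes, frames2[[11]]$nodes, tolerance = 1e-9)
  expect_error(generate_waveforms(cfg, beat = list(l = 19.9, period = -1,
                                                   Lambda = 19.9,
                                                   amplitude = 0.6,
                                                   psi0 = 0, n_nodes = 64)),
               "invalid beat model")
  # zero amplitude: straight rod, no motion between frames
  rodcfg <- synthetic_config(seed = 3, duration = 5e-3)
  rods <- generate_waveforms(rodcfg, beat = list(l = 10, period = 1 / 33,
                                                 Lambda = 10, amplitude = 0,
                                                 psi0 = 0, n_nodes = 64))
  expect_equal(rods[[1]]$nodes[, 2], rep(0, 64), tolerance = 1e-12)
  vels <- node_velocities(rods)
  expect_lt(max(abs(vels[[2]])), 1e-9)
})

test_that("the synthetic beat produces a nonzero propulsive mean force", {
  cfg <- synthetic_config(seed = 4, duration = 1 / 33)
  frames <- generate_waveforms(cfg, beat = list(l = 19.9, period = 1 / 33,
                                                Lambda = 19.9,
                                                amplitude = 0.6,
                                                psi0 = 0.25,
                                                n_nodes = 256))
  vels <- node_velocities(frames)
  cf <- lighthill_coefficients(1e-3, 80)
  Fs <- t(vapply(seq_along(frames), function(i)
    integrate_force(rft_force_density(frames[[i]], vels[[i]], cf))$F,
    numeric(2)))
  mean_F <- colMeans(Fs)
  typical <- mean(sqrt(rowSums(Fs^2)))
  expect_gt(sqrt(sum(mean_F^2)), 0.05 * typical)
})

test_that("phase pairs embed the simulated Delta exactly", {
  cfg <- synthetic_config(seed = 5, duration = 10)
  par <- adler_params(0.5, 1, 0.05, 33)
  pair <- generate_pair_phases(cfg, par, 33, L = 1.5)
  expect_equal((pair$phi1 - pair$phi2) / (2 * pi), pair$delta,
               tolerance = 1e-12)
  expect_equal(pair$delta, pair$ground_truth$delta)
  expect_equal(pair$L, 1.5)
  expect_error(generate_pair_phases(cfg, par, -1, L = 1), "positive")
  # deterministic relaxation and pure drift limits
  p_relax <- adler_params(0.5, 0, 0, 33)
  relax <- generate_pair_phases(cfg, p_relax, 33, L = 1, delta0 = 0.2)
  expect_true(all(diff(relax$delta) <= 1e-12))
  expect_lt(relax$delta[length(relax$delta)], 1e-4)
  p_drift <- adler_params(0, 0.8, 0, 33)
  drift <- generate_pair_phases(cfg, p_drift, 33, L = 1)
  expect_equal(drift$delta, 0.8 * drift$t, tolerance = 1e-9)
})

test_that("realistic-scale pairs at close separation stay mostly locked", {
  omega <- 33
  locked_fracs <- vapply(1:10, function(s) {
    cfg <- synthetic_config(seed = 800 + s, duration = 100)
    par <- adler_params(0.016 * omega / 0.85, 0.058 * omega,
                        0.005 * omega, omega)
    pair <- generate_pair_phases(cfg, par, omega, L = 0.85)
    detect_locked(pair)$locked_fraction
  }, numeric(1))
  expect_gt(min(locked_fracs), 0.9)
})

test_that("section signals round-trip through Poincare extraction", {
  omega <- 33
  cfg <- synthetic_config(seed = 6, duration = 20, noise_signal = 0)
  par <- adler_params(0, 0, 0, omega)
  pair <- generate_pair_phases(cfg, par, omega, L = 1)
  sig <- generate_section_signal(cfg, pair)
  ps <- poincare_phase(sig$t, sig$s1)
  # constant phase rate: mean recovered frequency 33 Hz
  f_rec <- (length(ps$crossings) - 1) / diff(range(ps$crossings))
  expect_equal(f_rec, omega, tolerance = 1e-3)
  expect_equal(diff(ps$crossings),
               rep(1 / omega, length(ps$crossings) - 1), tolerance = 1e-3)
  # waveshapes with several crossings per period are rejected
  expect_error(generate_section_signal(cfg, pair,
                                       waveshape = function(x) sin(2 * x)),
               "exactly once")
})

test_that("5 percent signal noise leaves the recovered Delta slip-free", {
  # the same phase pair is observed through clean and noisy signals; the
  # error attributable to the noise is the difference between the two
  # recoveries (once-per-beat sampling limits both identically)
  omega <- 33
  cfg_noisy <- synthetic_config(seed = 7, duration = 30,
                                noise_signal = 0.05)
  cfg_clean <- synthetic_config(seed = 7, duration = 30, noise_signal = 0)
  par <- adler_params(0.016 * omega, 0.02 * omega, 0.005 * omega, omega)
  pair <- generate_pair_phases(cfg_clean, par, omega, L = 1)
  recover <- function(sig) {
    ps1 <- poincare_phase(sig$t, sig$s1)
    ps2 <- poincare_phase(sig$t, sig$s2)
    phase_difference(ps1, ps2)
  }
  rec_n <- recover(generate_section_signal(cfg_noisy, pair))
  rec_c <- recover(generate_section_signal(cfg_clean, pair))
  tt <- seq(max(rec_n$t[1], rec_c$t[1]),
            min(max(rec_n$t), max(rec_c$t)), by = 1e-2)
  err <- approx(rec_n$t, rec_n$delta, xout = tt)$y -
    approx(rec_c$t, rec_c$delta, xout = tt)$y
  expect_lt(sqrt(mean((err - mean(err))^2)), 0.02)
  # no spurious windings caused by the noise
  expect_equal(round(err[length(err)] - err[1]), 0)
})
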