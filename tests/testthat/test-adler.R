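test_that("Euler-Maruyama integration reproduces the deterministic limits", {
  # pure drift: Delta(t) = Delta(0) + delta_nu t
  p <- adler_params(eps = 0, delta_nu = 1, T_eff = 0)
  sim <- simulate_adler(p, delta0 = 0.1, dt = 1e-3, duration = 5)
  expect_equal(sim$delta, 0.1 + sim$t, tolerance = 1e-9)
  # overdamped relaxation to the potential minimum at 0
  p2 <- adler_params(eps = 0.5, delta_nu = 0, T_eff = 0)
  sim2 <- simulate_adler(p2, delta0 = 0.2, dt = 1e-4, duration = 4)
  expect_true(all(diff(sim2$delta) <= 1e-12))
  expect_lt(abs(sim2$delta[length(sim2$delta)]), 1e-6)
  # with detuning the fixed point shifts to arcsin(delta_nu/2 pi eps)/2 pi
  p3 <- adler_params(eps = 0.5, delta_nu = 1, T_eff = 0)
  sim3 <- simulate_adler(p3, delta0 = 0.2, dt = 1e-4, duration = 4)
  expect_equal(sim3$delta[length(sim3$delta)],
               asin(1 / (2 * pi * 0.5)) / (2 * pi), tolerance = 1e-6)
  expect_error(simulate_adler(p3, dt = 0.1, duration = 1), "too coarse")
})

test_that("seeded simulations are reproducible", {
  p <- adler_params(eps = 0.3, delta_nu = 1, T_eff = 0.2)
  a <- simulate_adler(p, dt = 1e-3, duration = 2, seed = 99)
  b <- simulate_adler(p, dt = 1e-3, duration = 2, seed = 99)
  expect_identical(a$delta, b$delta)
})

test_that("locked-state variance matches the OU linearisation", {
  p <- adler_params(eps = 0.528, delta_nu = 0, T_eff = 0.04)
  sim <- simulate_adler(p, delta0 = 0, dt = 1e-4, duration = 100,
                        seed = 12)
  pred <- p$T_eff / (4 * pi^2 * p$eps)
  expect_equal(var(sim$delta), pred, tolerance = 0.1)
})

test_that("symmetry (delta_nu, Delta) -> (-delta_nu, -Delta) holds", {
  p <- adler_params(eps = 0.4, delta_nu = 0.8, T_eff = 0)
  pm <- adler_params(eps = 0.4, delta_nu = -0.8, T_eff = 0)
  a <- simulate_adler(p, delta0 = 0.31, dt = 1e-3, duration = 5)
  b <- simulate_adler(pm, delta0 = -0.31, dt = 1e-3, duration = 5)
  expect_equal(b$delta, -a$delta, tolerance = 1e-12)
})

test_that("noise-free frequency difference follows the locking formula", {
  expect_equal(predicted_freq_diff(0, 1.9), 1)
  expect_equal(predicted_freq_diff(1.9 / (2 * pi), 1.9), 0)
  expect_equal(predicted_freq_diff(0.5 * 1.9 / (2 * pi), 1.9),
               sqrt(3) / 2)
  expect_error(predicted_freq_diff(0.1, 0), "non-zero")
  # simulation oracle: deterministic mean drift over many windings
  delta_nu <- 1.914
  for (ratio in c(0.5, 0.9)) {
    p <- adler_params(eps = ratio * delta_nu / (2 * pi),
                      delta_nu = delta_nu, T_eff = 0)
    sim <- simulate_adler(p, dt = 1e-4, duration = 300, thin = 100L)
    n <- length(sim$delta)
    drift <- (sim$delta[n] - sim$delta[1]) / (sim$t[n] - sim$t[1])
    expect_equal(drift / delta_nu, predicted_freq_diff(p$eps, delta_nu),
                 tolerance = 0.01)
  }
})

test_that("noise rounds the frequency-difference bifurcation", {
  delta_nu <- 1.914
  # T_eff = 0 reduces to the deterministic prediction
  p0 <- adler_params(eps = 0.5 * delta_nu / (2 * pi), delta_nu = delta_nu,
                     T_eff = 0)
  nf <- noisy_freq_diff(p0, duration = 200, seeds = 1:2)
  expect_equal(nf$value, sqrt(3) / 2, tolerance = 0.01)
  # exactly at the deterministic bifurcation, noise gives strictly
  # positive drift
  pc <- adler_params(eps = delta_nu / (2 * pi), delta_nu = delta_nu,
                     T_eff = 0.15)
  nfc <- noisy_freq_diff(pc, duration = 60, seeds = 1:10)
  expect_gt(nfc$value, 0.02)
  expect_true(all(nfc$drifts >= 0))
  # monotone in the noise strength at fixed 2 pi eps / delta_nu = 1.1
  p_lo <- adler_params(eps = 1.1 * delta_nu / (2 * pi),
                       delta_nu = delta_nu, T_eff = 0.05)
  p_hi <- adler_params(eps = 1.1 * delta_nu / (2 * pi),
                       delta_nu = delta_nu, T_eff = 0.3)
  v_lo <- noisy_freq_diff(p_lo, duration = 60, seeds = 1:6)$value
  v_hi <- noisy_freq_diff(p_hi, duration = 60, seeds = 1:6)$value
  expect_gt(v_hi, v_lo)
})

test_that("autocovariance fit recovers Ornstein-Uhlenbeck parameters", {
  set.seed(17)
  r <- 10; D <- 0.5; dt <- 1e-3
  x <- oracle_ou(1e5, r, D, dt, x0 = 0)[-(1:2000)]   # drop transient
  ac <- adler_autocorrelation(x, dt)
  expect_equal(ac$C0, D / r, tolerance = 0.1)
  expect_equal(ac$tau_r, 1 / r, tolerance = 0.1)
  expect_identical(ac$flag, "ok")
  # white noise: decay unresolved at this sampling, flagged
  acw <- adler_autocorrelation(rnorm(5000), dt)
  expect_identical(acw$flag, "white")
  # locked run: C0 equals the sample variance (stationarity identity)
  p <- adler_params(eps = 0.528, delta_nu = 0, T_eff = 0.04)
  sim <- simulate_adler(p, dt = 1e-4, duration = 100, seed = 3,
                        thin = 10L)
  ac2 <- adler_autocorrelation(sim$delta - mean(sim$delta), sim$dt)
  expect_equal(ac2$C0, var(sim$delta), tolerance = 0.05)
})

test_that("both inference routes recover the generating triple", {
  omega <- 33
  true <- c(0.016 * omega, 0.058 * omega, 0.005 * omega)
  res <- lapply(1:6, function(s) {
    cfg <- synthetic_config(seed = 700 + s, duration = 100)
    par <- adler_params(true[1], true[2], true[3], omega)
    pair <- generate_pair_phases(cfg, par, omega, L = 1)
    list(inc = coef(infer_adler(pair)),
         acv = coef(infer_adler(pair, method = "autocorrelation")))
  })
  for (m in c("inc", "acv")) {
    est <- t(vapply(res, function(x) x[[m]][1:3], numeric(3)))
    rel <- abs(sweep(est, 2, true)) / rep(true, each = 6)
    expect_lt(max(apply(rel, 2, median)), 0.2)
  }
})

test_that("inference handles noiseless, antiphase and drifting series", {
  omega <- 33
  # noiseless locked series: T_eff estimate essentially zero
  p0 <- adler_params(0.016 * omega, 0.058 * omega, 0, omega)
  pair0 <- generate_pair_phases(synthetic_config(seed = 41, duration = 30),
                                p0, omega, L = 1)
  expect_lt(infer_adler(pair0)$params$T_eff, 1e-3 * omega)
  # antiphase pair locked near Delta0 = 1/2: negative coupling
  pA <- adler_params(-0.016 * omega, 0.058 * omega, 0.005 * omega, omega)
  pairA <- generate_pair_phases(synthetic_config(seed = 42, duration = 60),
                                pA, omega, L = 1, delta0 = 0.5,
                                orientation = "AP")
  fitA <- infer_adler(pairA)
  expect_lt(fitA$params$eps, 0)
  expect_equal(fitA$params$eps, pA$eps, tolerance = 0.2)
  fitA2 <- infer_adler(pairA, method = "autocorrelation")
  expect_lt(fitA2$params$eps, 0)
  # never-locked drifting series: autocorrelation route falls back to a
  # drift-only delta_nu estimate
  pD <- adler_params(0, 3, 0.02, omega)
  pairD <- generate_pair_phases(synthetic_config(seed = 43, duration = 30),
                                pD, omega, L = 1)
  fitD <- infer_adler(pairD, method = "autocorrelation", hold = 2)
  expect_false(fitD$resolved)
  expect_equal(fitD$params$delta_nu, 3, tolerance = 0.05)
  expect_true(is.na(fitD$params$eps))
})

test_that("deterministic locked runs never slip; noise raises the rate", {
  omega <- 33
  p <- adler_params(0.6, 1.2, 0, omega)
  pair <- generate_pair_phases(synthetic_config(seed = 51, duration = 60),
                               p, omega, L = 1)
  expect_equal(nrow(detect_locked(pair)$slips), 0)
  # slip rate increases with T_eff and decreases with eps (3 x 3 grid)
  count <- function(eps, teff, seed) {
    pp <- adler_params(eps, 1.2, teff, omega)
    pr <- generate_pair_phases(synthetic_config(seed = seed, duration = 60),
                               pp, omega, L = 1)
    nrow(detect_locked(pr)$slips)
  }
  eps_grid <- c(0.3, 0.5, 0.8)
  teff_grid <- c(0.05, 0.15, 0.45)
  n_slips <- outer(seq_along(eps_grid), seq_along(teff_grid),
                   Vectorize(function(i, j)
                     count(eps_grid[i], teff_grid[j], 60 + 10 * i + j)))
  for (i in 1:3) expect_true(all(diff(n_slips[i, ]) >= 0))
  for (j in 1:3) expect_true(all(diff(n_slips[, j]) <= 0))
  expect_gt(n_slips[1, 3], n_slips[3, 1])
})

test_that("the coupling law fit extracts k and checks the exponent", {
  L <- c(0.85, 1.22, 1.69, 2.27)
  fit <- fit_coupling_law(L, 0.016 / L, orientation = "IP")
  expect_equal(fit$k, 0.016, tolerance = 1e-12)
  expect_equal(fit$loglog_slope, -1, tolerance = 1e-9)
  # doubling kappa doubles k
  expect_equal(fit_coupling_law(L, 2 * 0.016 / L)$k, 0.032,
               tolerance = 1e-12)
  # 10 percent multiplicative noise, 8 separations
  set.seed(23)
  L8 <- seq(0.8, 2.4, length.out = 8)
  ks <- vapply(1:100, function(s) {
    fit_coupling_law(L8, (0.016 / L8) * (1 + rnorm(8, sd = 0.1)))$k
  }, numeric(1))
  expect_lt(abs(median(ks) - 0.016) / 0.016, 0.1)
  expect_error(fit_coupling_law(c(1, 1), c(1, 1)), "distinct")
})

test_that("beat-period statistics give the single-cell noise strength", {
  # first-passage oracle: noisy oscillator with known phase diffusion
  f <- 33; D <- 0.1
  set.seed(8)
  periods <- flagsync:::noisy_oscillator_periods_cpp(f, D, 1e-5, 1000)
  est <- teff_from_periods(periods)
  expect_equal(est$D1, D, tolerance = 0.15)
  # zero-noise oscillator: estimate zero
  expect_equal(teff_from_periods(rep(1 / f, 200))$D1, 0)
  # quadrupling the period variance quadruples the estimate
  p4 <- mean(periods) + 2 * (periods - mean(periods))
  expect_equal(teff_from_periods(p4)$D1, 4 * est$D1, tolerance = 1e-9)
  # a pair sums the two single-cell diffusions
  expect_equal(teff_from_periods(periods, periods)$T_eff, 2 * est$D1)
})
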