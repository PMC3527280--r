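test_that("phase differences wrap, cancel for identical signals, and are antisymmetric", {
  f <- fix_meso()
  pd_self <- phase_difference(f$aL, f$aL)
  expect_true(all(abs(pd_self$phi[pd_self$valid]) < 1e-12))
  pd <- phase_difference(f$aL, f$aR)
  pd_rev <- phase_difference(f$aR, f$aL)
  ok <- pd$valid
  expect_equal(wrap_angle(pd$phi[ok] + pd_rev$phi[ok]), rep(0, sum(ok)),
               tolerance = 1e-12)
  expect_true(all(pd$phi >= -pi & pd$phi < pi))
  short <- filter_signal(rnorm(3000), 28)
  expect_error(phase_difference(f$aL, short), "lengths differ")
  other <- filter_signal(f$meso$s_R, 25)
  expect_error(phase_difference(f$aL, other), "frequencies differ")
})

test_that("a quarter-cycle delay appears as a +pi/2 phase difference", {
  fs <- 1000; v0 <- 25                      # quarter period = 10 samples
  t <- (0:19999) / fs
  x <- cos(2 * pi * v0 * t)
  left <- filter_signal(x, v0, fs = fs)
  right <- filter_signal(c(rep(0, 10), x[1:(length(x) - 10)]), v0, fs = fs)
  pd <- phase_difference(left, right)
  ok <- which(pd$valid); ok <- ok[ok > 500 & ok < 19500]
  expect_equal(mean(wrap_angle(pd$phi[ok])), pi / 2, tolerance = 1e-3)
})

test_that("inter-hemispheric phase difference is independent of local phase", {
  f <- fix_meso()
  pd <- phase_difference(f$aL, f$aR)
  ok <- pd$valid
  expect_lt(abs(circ_cor(pd$phi[ok], clc_phase(f$aL)[ok])), 0.1)
})

test_that("von Mises density estimation recovers mean and concentration", {
  set.seed(20)
  for (kappa in c(0.5, 2, 8)) {
    x <- rvonmises(20000, mu = 0.3, kappa = kappa)
    d <- fit_phase_diff_distribution(x)
    expect_equal(d$mu, 0.3, tolerance = 0.1)
    expect_equal(d$kappa, kappa, tolerance = 0.1 * max(kappa, 1) / max(kappa, 1e-9))
  }
  # uniform angles: concentration near zero
  du <- fit_phase_diff_distribution(runif(20000, -pi, pi))
  expect_lt(du$kappa, 0.05)
  expect_equal(sum(du$density), 1, tolerance = 1e-12)
  # degenerate series: capped with a warning
  expect_warning(dg <- fit_phase_diff_distribution(rep(0.2, 2000)), "capped")
  expect_equal(dg$kappa, 50)
  expect_error(fit_phase_diff_distribution(runif(100, -pi, pi)), "1000")
})

test_that("kappa-hat estimator bias shrinks with sample size", {
  set.seed(21)
  bias <- vapply(c(200, 2000, 20000), function(n)
    mean(vapply(1:20, function(i)
      vm_A_inv(circ_mean_R(rvonmises(n, 0, 2))$R), numeric(1))) - 2,
    numeric(1))
  expect_true(abs(bias[3]) < abs(bias[1]))
  expect_lt(abs(bias[3]), 0.05)
})

test_that("the generator's inter-hemispheric offsets concentrate near zero", {
  f <- fix_meso()
  d <- fit_phase_diff_distribution(phase_difference(f$aL, f$aR))
  expect_lt(abs(d$mu), 0.3)
  expect_gt(d$kappa, 0.3)
})

test_that("conditioned mean amplitudes conserve the global mean exactly", {
  f <- fix_meso()
  pd <- phase_difference(f$aL, f$aR)
  aL <- clc_amplitude(f$aL); aR <- clc_amplitude(f$aR)
  lc <- lagged_amplitude_conditioning(pd, aL, aR, lags_ms = 0, n_bins = 16)
  cv <- lc$curves[[1]]
  ok <- pd$valid
  N_t <- cv$P * 16
  expect_equal(mean(cv$mean_L), mean(aL[ok][seq_len(N_t)]), tolerance = 1e-12)
  expect_error(lagged_amplitude_conditioning(pd, aL, aR, lags_ms = numeric(0)),
               "empty lag")
})

test_that("phase-difference-gated amplitudes are detected at the configured lag", {
  tr <- NULL
  m <- generate_meso_lfp(NULL, 180000, seed = 61, desync_profile = NULL,
                         opts = utils::modifyList(meso_defaults(),
                           list(delta_tau_ms = 100,
                                pd_gate = list(lag_ms = 26, gain = 0.6,
                                               corr_mix = 0.45))))
  aL <- normalize_amplitude(filter_signal(m$s_L, 28))
  aR <- normalize_amplitude(filter_signal(m$s_R, 28))
  pd <- phase_difference(aL, aR)
  lc <- lagged_amplitude_conditioning(pd, clc_amplitude(aL), clc_amplitude(aR),
                                      lags_ms = seq(-60, 60, by = 4),
                                      n_bins = 8)
  expect_lt(abs(lc$best_lag_mean - 26), 9)
  # conditioned mean amplitude depends on the phase difference at the lag
  best <- lc$curves[[which(lc$ranges$lag == lc$best_lag_mean)]]
  expect_gt(diff(range(best$mean_L)), 0.15)
  # amplitude correlation varies across phase-difference bins when gated
  expect_gt(max(lc$ranges$range_corr), 0.2)
  # independence control: amplitudes truly independent of the phase
  # difference give flat conditioned means and near-zero correlation range
  set.seed(63)
  n0 <- 120000
  pd0 <- structure(list(phi = rvonmises(n0, 0, 1), valid = rep(TRUE, n0),
                        fs = 1000, v0 = 28), class = "phase_diff")
  e0L <- exp(rnorm(n0, 0, 0.4)); e0L <- e0L / mean(e0L)
  e0R <- exp(rnorm(n0, 0, 0.4)); e0R <- e0R / mean(e0R)
  lc0 <- lagged_amplitude_conditioning(pd0, e0L, e0R,
                                       lags_ms = c(-26, 0, 26), n_bins = 8)
  expect_lt(max(lc0$ranges$range_mean), 0.05)
  expect_lt(max(lc0$ranges$range_corr), 0.08)
  expect_equal(mean(lc0$curves[[2]]$mean_L), 1, tolerance = 0.02)
})
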