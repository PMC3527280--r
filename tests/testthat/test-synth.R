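test_that("trial tables obey the task timing grammar", {
  for (task in c("MC", "BC")) {
    tr <- fix_trials_fixed(task, 8, seed = 1)
    hold <- if (task == "MC") 500 else 100
    thold <- if (task == "MC") 400 else 50
    expect_true(all(tr$t_go - tr$t_center_enter == hold))
    expect_true(all(tr$t_reward_on - tr$t_target_enter == thold))
    expect_true(all(tr$t_reward_off - tr$t_reward_on == 500))
    expect_true(all(tr$movement_duration == 900))
    ts <- as.matrix(tr[, c("t_center_on", "t_center_enter", "t_go",
                           "t_target_enter", "t_reward_on", "t_reward_off")])
    expect_true(all(apply(ts, 1, diff) > 0))
  }
})

test_that("targets are balanced and generation is deterministic", {
  tr <- generate_trials("MC", 800, list(dist = "uniform", min = 400,
                                        max = 3000), seed = 7)
  counts <- table(factor(tr$target_id, levels = 1:8))
  expect_true(all(abs(counts - 100) <= 1))
  expect_true(all(tr$movement_duration <= 10000))
  tr2 <- generate_trials("MC", 800, list(dist = "uniform", min = 400,
                                         max = 3000), seed = 7)
  expect_identical(tr, tr2)
})

test_that("trial generation rejects invalid inputs", {
  expect_error(generate_trials("XX", 5), "invalid task")
  expect_error(generate_trials("MC", 0), "positive")
  expect_error(generate_trials("MC", 5, list(dist = "fixed", value = 20000)),
               "outside")
  expect_error(generate_trials("MC", 5, list(dist = "bogus")), "unknown")
})

test_that("meso generator hits its spectral calibration", {
  f <- fix_meso()
  pk <- psd_peak(welch_psd(f$meso$s_L, 1000))
  expect_equal(pk$freq, 28, tolerance = 0.5 / 28)
  expect_equal(pk$level_db, -46, tolerance = 1 / 46)
  pkR <- psd_peak(welch_psd(f$meso$s_R, 1000))
  expect_equal(pkR$freq, 28, tolerance = 0.5 / 28)
})

test_that("beta envelope dips after the go cue and rises during reward", {
  f <- fix_meso()
  ev <- event_locked_average(f$aL, f$trials$t_go, c(-800, 1400))
  pre <- mean(ev$mean[ev$time < -100])
  move <- mean(ev$mean[ev$time > 150 & ev$time < 500])
  expect_lt(move, 0.9 * pre)
  evr <- event_locked_average(f$aL, f$trials$t_reward_on, c(-100, 400))
  expect_gt(mean(evr$mean[evr$time > 100]), move)
})

test_that("without trials and desynchronization the envelope is stationary", {
  m0 <- generate_meso_lfp(NULL, 40000, seed = 8, desync_profile = NULL)
  a <- normalize_amplitude(filter_signal(m0$s_L, 28))
  fake_go <- seq(3000, 37000, by = 700)
  ev <- event_locked_average(a, fake_go, c(-500, 500))
  # no systematic pre/post contrast and no event-locked dip
  expect_lt(abs(mean(ev$mean[ev$time > 0]) - mean(ev$mean[ev$time < 0])), 0.1)
  expect_lt(diff(range(ev$mean)), 0.4)
  expect_equal(mean(ev$mean), 1, tolerance = 0.1)
})

test_that("meso generation is reproducible and validates duration", {
  tr <- fix_trials_fixed("MC", 4, seed = 3)
  m1 <- generate_meso_lfp(tr, trial_span(tr) + 2000, seed = 5)
  m2 <- generate_meso_lfp(tr, trial_span(tr) + 2000, seed = 5)
  expect_identical(m1$s_L, m2$s_L)
  expect_identical(m1$s_R, m2$s_R)
  expect_error(generate_meso_lfp(tr, trial_span(tr) - 1000, seed = 5),
               "shorter than the trial span")
})

test_that("spike generator reproduces its ground-truth rate structure", {
  f <- fix_meso()
  # homogeneous unit: empirical rate within 3 SE of baseline
  gt0 <- unit_ground_truth("u0", MC = unit_params(r_baseline = 20),
                           BC = unit_params(r_baseline = 20))
  s <- generate_spikes(gt0, "MC", f$aL, seed = 11)
  n <- length(s$x)
  se <- sqrt(20 / (n / 1000))
  expect_equal(sum(s$x) / n * 1000, 20, tolerance = 3 * se / 20)
  # pure cosine term: spike-phase circular mean at the preferred phase
  gtc <- unit_ground_truth("uc",
    MC = unit_params(r_baseline = 20, phase = c(b1 = 8, b2 = 0, pref = 1)),
    BC = unit_params(r_baseline = 20))
  sc <- generate_spikes(gtc, "MC", f$aL, seed = 12)
  ph <- clc_phase(f$aL)[sc$x == 1L & f$aL$valid]
  expect_equal(circ_mean_R(ph)$mu, 1, tolerance = 0.15)
  # sign-flipped sigmoid across tasks: amplitude-conditioned slopes oppose
  gtf <- unit_ground_truth("uf",
    MC = unit_params(r_baseline = 20, amp = c(p2 = 6, p3 = 1, p4 = 0.2)),
    BC = unit_params(r_baseline = 20, amp = c(p2 = -6, p3 = 1, p4 = 0.2)))
  s_mc <- generate_spikes(gtf, "MC", f$aL, seed = 13)
  s_bc <- generate_spikes(gtf, "BC", f$aL, seed = 14)
  f_mc <- clc_fit(f$aL, s_mc, "amplitude")
  f_bc <- clc_fit(f$aL, s_bc, "amplitude")
  expect_gt(coef(f_mc)[["p2"]], 0)
  expect_lt(coef(f_bc)[["p2"]], 0)
  # saturation guard
  gtx <- unit_ground_truth("ux", MC = unit_params(r_baseline = 999,
                                                  amp = c(p2 = 500, p3 = 1, p4 = 0.2)),
                           BC = unit_params())
  expect_error(generate_spikes(gtx, "MC", f$aL), "1000 spikes/s")
})

test_that("ground truth exports round-trip losslessly", {
  gts <- synthesize_units(3, seed = 21)
  path <- tempfile(fileext = ".json")
  export_ground_truth(gts, path)
  back <- read_ground_truth(path)
  expect_equal(back, gts)
  # record includes both task parameter sets per unit
  raw <- jsonlite::read_json(path)
  expect_true(all(vapply(raw, function(u)
    all(c("MC", "BC") %in% names(u)), logical(1))))
  expect_error(export_ground_truth(gts, "/nonexistent-dir-xyz/gt.json"),
               "nonexistent-dir-xyz")
})

test_that("array generator degenerate mode yields identical channels at the cap", {
  m0 <- generate_meso_lfp(NULL, 30000, seed = 31, desync_profile = NULL)
  arr <- generate_array_lfp(m0, "L", grid = electrode_grid(3), jitter = FALSE,
                            seed = 32)
  expect_equal(arr$lfp[, 1], arr$lfp[, 9])
  dk <- distance_kappa_fit(arr)
  expect_true(dk$degenerate)
  expect_true(all(dk$table$kappa == dk$cap))
  expect_error(generate_array_lfp(m0, "L", kappa_law = c(1, -0.4435),
                                  seed = 1), "non-positive")
})

test_that("spatial average tracks the meso signal and warns off 64 channels", {
  f <- fix_meso()
  arr <- generate_array_lfp(f$meso, "L", grid = electrode_grid(4), seed = 33,
                            cal_dur_s = 30, n_cal = 1)
  expect_warning(avg <- spatial_average(arr), "64")
  expect_equal(avg, rowMeans(arr$lfp))
  expect_gt(stats::cor(avg, f$meso$s_L), 0.95)
})

test_that("pairwise concentration decreases with distance on a small array", {
  f <- fix_meso()
  arr <- generate_array_lfp(f$meso, "L", grid = electrode_grid(4), seed = 34,
                            cal_dur_s = 45, n_cal = 2)
  dk <- distance_kappa_fit(arr)
  expect_false(dk$degenerate)
  expect_lt(dk$slope, 0)
  expect_lt(stats::cor(dk$table$distance, dk$table$kappa), -0.8)
})
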