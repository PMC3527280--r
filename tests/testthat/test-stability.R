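# Ensemble datasets for split-half / cross-task comparisons: two tasks with
# remapped or shared ground truth, built once.
fix_two_tasks <- function() fixture("two_tasks", function() {
  gts <- synthesize_units(6, seed = 50, remap = TRUE)
  data <- lapply(c(MC = "MC", BC = "BC"), function(task) {
    trials <- generate_trials(task, 30,
                              movement_duration_law = list(dist = "uniform",
                                                           min = 500, max = 1500),
                              seed = 51 + match(task, c("MC", "BC")))
    meso <- generate_meso_lfp(trials, max(120000, trial_span(trials) + 6000),
                              seed = 53 + match(task, c("MC", "BC")))
    aL <- normalize_amplitude(filter_signal(meso$s_L, 28))
    spikes <- lapply(seq_along(gts), function(i)
      generate_spikes(gts[[i]], task, aL, trials = trials, seed = 60 + i +
                        100 * match(task, c("MC", "BC"))))
    list(analytic = aL, spikes = spikes, trials = trials, meso = meso)
  })
  list(gts = gts, data = data)
})

test_that("identical task datasets give identical within- and cross-task correlations", {
  tt <- fix_two_tasks()
  same <- list(MC = tt$data$MC, BC = tt$data$MC)
  cmp <- split_half_compare(same, "amplitude")
  # duplicated data: the matched-half cross pairings are exactly identical
  expect_equal(unname(cmp$correlations[["BC1_MC1"]]), 1, tolerance = 1e-12)
  expect_equal(unname(cmp$correlations[["BC2_MC2"]]), 1, tolerance = 1e-12)
  expect_equal(unname(cmp$correlations[["BC1_BC2"]]),
               unname(cmp$correlations[["MC1_MC2"]]), tolerance = 1e-12)
})

test_that("a remapped ensemble is more stable within than across tasks", {
  tt <- fix_two_tasks()
  cmp <- split_half_compare(tt$data, "amplitude")
  expect_gt(cmp$within, 0.6)            # within-task halves agree
  expect_gt(cmp$within, cmp$cross)      # cross-task remapping decorrelates
  # preferred-phase comparison: same ordering
  cmpp <- split_half_compare(tt$data, "phase")
  expect_gt(cmpp$within, cmpp$cross)
})

test_that("split halves recover a shared ground truth consistently", {
  tt <- fix_two_tasks()
  d <- tt$data$MC
  u <- which.max(vapply(tt$gts, function(g) abs(g$MC$amp[["p2"]]), numeric(1)))
  sh <- split_half_fits(d$analytic, d$spikes[[u]], d$trials, "amplitude")
  rc1 <- diff(predict(sh$half1, c(0.6, 1.6)))
  rc2 <- diff(predict(sh$half2, c(0.6, 1.6)))
  true_rc <- diff(F_S(c(0.6, 1.6), c(0, tt$gts[[u]]$MC$amp)))
  expect_equal(sign(rc1), sign(true_rc))
  expect_equal(sign(rc2), sign(true_rc))
  expect_lt(abs(rc1 - rc2), abs(true_rc) + 3)
  expect_error(split_half_fits(d$analytic, d$spikes[[1]], d$trials[1, ],
                               "amplitude"))
})

test_that("amplitude-quartile conditioning reveals amplitude-gated phase depth", {
  m <- generate_meso_lfp(NULL, 240000, seed = 55, desync_profile = NULL)
  aL <- normalize_amplitude(filter_signal(m$s_L, 28))
  gt <- unit_ground_truth("g",
    MC = unit_params(r_baseline = 20, phase = c(b1 = 0, b2 = 8, pref = 1)),
    BC = unit_params())
  s <- generate_spikes(gt, "MC", aL, seed = 56)
  fits <- conditional_mapping(aL, s, condition = "amplitude_quartile",
                              what = "phase", n_bins = 16)
  depth <- vapply(fits, function(f) coef(f)[["p2"]], numeric(1))
  expect_length(depth, 4)
  expect_true(all(diff(depth) > 0))      # monotone across quartiles
  # preferred phase stable across quartiles
  # (lowest quartile has little phase modulation, so its angle is noisy)
  prefs <- vapply(fits[2:4], function(f) coef(f)[["p3"]], numeric(1))
  expect_lt(max(abs(wrap_angle(prefs - 1))), 0.35)
})

test_that("target conditioning recovers the configured direction tuning", {
  tt <- fix_two_tasks()
  gt <- unit_ground_truth("t",
    MC = unit_params(r_baseline = 20, target = c(depth = 8, pref = 3)),
    BC = unit_params())
  d <- tt$data$MC
  s <- generate_spikes(gt, "MC", d$analytic, trials = d$trials, seed = 57)
  fits <- conditional_mapping(d$analytic, s, d$trials, condition = "target",
                              what = "phase", n_bins = 12)
  base <- vapply(fits, function(f) coef(f)[["p1"]], numeric(1))
  expected <- 20 + 8 * cos(2 * pi * ((1:8) - 3) / 8)
  expect_gt(stats::cor(base, expected), 0.9)
  # empty condition errors: no trials at all in the window
  empty_trials <- d$trials[0, ]
  expect_error(conditional_mapping(d$analytic, s, empty_trials,
                                   condition = "target"), "empty condition")
})

test_that("trial-stage conditioning uses the documented stage windows", {
  tt <- fix_two_tasks()
  d <- tt$data$MC
  gt <- unit_ground_truth("s",
    MC = unit_params(r_baseline = 15, trial = c(move = 10, reward = -5)),
    BC = unit_params())
  s <- generate_spikes(gt, "MC", d$analytic, trials = d$trials, seed = 58)
  fits <- conditional_mapping(d$analytic, s, d$trials, condition = "stage",
                              what = "amplitude", n_bins = 10)
  base <- vapply(fits, function(f) mean(f$mapping$R), numeric(1))
  expect_gt(base[["move_to_target"]], base[["move_to_center"]] + 5)
  expect_lt(base[["reward"]], base[["move_to_center"]])
})

test_that("external tuning components are learned and transfer to held-out trials", {
  tt <- fix_two_tasks()
  d <- tt$data$MC
  gt <- unit_ground_truth("e",
    MC = unit_params(r_baseline = 18, trial = c(move = 8, reward = -4),
                     target = c(depth = 6, pref = 5)),
    BC = unit_params())
  s <- generate_spikes(gt, "MC", d$analytic, trials = d$trials, seed = 59)
  odd <- d$trials[d$trials$trial_id %% 2 == 1, ]
  even <- d$trials[d$trials$trial_id %% 2 == 0, ]
  et <- external_tuning(s, odd)
  # components reflect the generator
  expect_equal(et$r_baseline, 18, tolerance = 0.15)
  expect_gt(stats::cor(et$r_target, 6 * cos(2 * pi * ((1:8) - 5) / 8)), 0.7)
  # held-out prediction: binned predicted-vs-measured slope near 1
  pred <- predict(et, even, length(s$x))
  keep <- sample_trial_id(even, length(s$x)) > 0
  ev <- evaluate_prediction(pred[keep], s$x[keep], n_bins = 10)
  expect_equal(ev$slope, 1, tolerance = 0.3)
  # idempotence: refitting on the same data reproduces the components
  et2 <- external_tuning(s, odd)
  expect_identical(et$r_trial, et2$r_trial)
  expect_identical(et$r_target, et2$r_target)
  # untuned homogeneous unit: components ~ 0
  s0 <- generate_spikes(unit_ground_truth("h", MC = unit_params(20),
                                          BC = unit_params(20)),
                        "MC", d$analytic, seed = 60)
  et0 <- external_tuning(s0, d$trials)
  expect_lt(max(abs(et0$r_target)), 3)
  expect_lt(max(abs(et0$r_trial$rate)), 4)
})

test_that("frequency profiles localize amplitude and phase coupling bands", {
  m <- generate_meso_lfp(NULL, 180000, seed = 70, desync_profile = NULL)
  bank <- data.frame(v0 = c(16, 21, 27, 34, 42))
  bank$s0 <- gabor_s0(bank$v0 * gabor_sigma_f(-5.075) / 28)
  a27 <- normalize_amplitude(filter_signal(m$s_L, 27))
  a34 <- normalize_amplitude(filter_signal(m$s_L, 34))
  # dissociated coupling: amplitude at 27 Hz, phase at 34 Hz
  rate <- pmax(20 + 8 * tanh((clc_amplitude(a27) - 1) / 0.4) +
                 6 * cos(clc_phase(a34) - 1), 0)
  rate[!a27$valid | !a34$valid] <- 20
  set.seed(71)
  s <- rbinom(length(rate), 1, rate / 1000)
  prof <- frequency_profile(m$s_L, s, bank)
  expect_equal(prof$v0[which.max(prof$amp_range)], 27)
  expect_equal(prof$v0[which.max(prof$phase_range)], 34)
  # uncoupled unit: both profiles flat near zero
  s0 <- rbinom(length(rate), 1, 0.02)
  prof0 <- frequency_profile(m$s_L, s0, bank)
  expect_lt(max(prof0$amp_range), 0.25 * max(prof$amp_range))
  expect_lt(max(prof0$phase_range), 0.25 * max(prof$phase_range))
})
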