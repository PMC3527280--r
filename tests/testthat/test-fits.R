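test_that("all four families recover exact parameters from noiseless curves", {
  A <- seq(0.3, 2.5, length.out = 25)
  th <- seq(-pi + 0.1, pi - 0.1, length.out = 25)
  ps <- c(10, -4, 1, 0.2)
  fs <- fit_sigmoid(mk_mapping(A, F_S(A, ps)))
  expect_equal(unname(coef(fs)), ps, tolerance = 1e-6)
  pc <- c(20, 5, 1)
  fc <- fit_cosine(mk_mapping(th, F_C(th, pc), "phase"))
  expect_equal(unname(coef(fc)), pc, tolerance = 1e-9)
  pd <- c(2, 3, 1.5, 0)
  fd <- fit_vonmises_rate(mk_mapping(th, F_D(th, pd), "phase_diff"))
  expect_equal(unname(coef(fd)), pd, tolerance = 1e-5)
  # joint: exact cell rates on a support grid
  amp_sup <- seq(0.4, 2.2, length.out = 8)
  ph_sup <- matrix(rep(th[1:16], each = 8), 8, 16)
  pb <- c(25, -6, 1, 0.2, 3, 0.8, 1)
  jb <- structure(list(rates = F_B(amp_sup[row(ph_sup)], ph_sup, pb),
                       amp_support = amp_sup, phase_support = ph_sup,
                       P = 1000, N = 128000, N_t = 128000, n_ab = 8,
                       n_pb = 16, fs = 1000),
                  class = "joint_binning")
  fb <- fit_beta_rate(jb)
  expect_equal(unname(coef(fb)), pb, tolerance = 1e-4)
  expect_equal(fb$b1, pb[5], tolerance = 1e-4)
  expect_equal(fb$b2, pb[6], tolerance = 1e-4)
})

test_that("flat mappings collapse to the degenerate fits", {
  A <- seq(0.3, 2.5, length.out = 25)
  th <- seq(-pi + 0.1, pi - 0.1, length.out = 25)
  fs <- fit_sigmoid(mk_mapping(A, rep(12, 25)))
  expect_lt(abs(coef(fs)[["p2"]]), 1e-6)
  expect_equal(coef(fs)[["p1"]], 12, tolerance = 1e-6)
  fc <- fit_cosine(mk_mapping(th, rep(12, 25), "phase"))
  expect_lt(coef(fc)[["p2"]], 1e-9)
  fd <- fit_vonmises_rate(mk_mapping(th, rep(12, 25), "pd"))
  expect_lt(fd$modulation, 1e-6)
})

test_that("cosine fit is equivariant under phase rotation and rate offset", {
  th <- seq(-pi + 0.13, pi - 0.13, length.out = 24)
  pc <- c(20, 5, 1)
  base <- coef(fit_cosine(mk_mapping(th, F_C(th, pc), "phase")))
  for (delta in c(0.7, -2.1)) {
    sh <- coef(fit_cosine(mk_mapping(wrap_angle(th + delta),
                                     F_C(th, pc), "phase")))
    expect_equal(sh[["p1"]], base[["p1"]], tolerance = 1e-8)
    expect_equal(sh[["p2"]], base[["p2"]], tolerance = 1e-8)
    expect_equal(wrap_angle(sh[["p3"]] - base[["p3"]] - delta), 0,
                 tolerance = 1e-8)
  }
  # adding a constant shifts only the offsets, for every family
  A <- seq(0.3, 2.5, length.out = 25)
  ps <- c(10, -4, 1, 0.2)
  f0 <- coef(fit_sigmoid(mk_mapping(A, F_S(A, ps))))
  f7 <- coef(fit_sigmoid(mk_mapping(A, F_S(A, ps) + 7)))
  expect_equal(f7[["p1"]] - f0[["p1"]], 7, tolerance = 1e-5)
  expect_equal(f7[2:4], f0[2:4], tolerance = 1e-4)
  pdp <- c(2, 3, 1.5, 0)
  d0 <- coef(fit_vonmises_rate(mk_mapping(th, F_D(th, pdp), "pd")))
  d7 <- coef(fit_vonmises_rate(mk_mapping(th, F_D(th, pdp) + 7, "pd")))
  expect_equal(d7[["p1"]] - d0[["p1"]], 7, tolerance = 1e-4)
  expect_equal(d7[2:4], d0[2:4], tolerance = 1e-3)
})

test_that("width p4 is constrained positive so p2 carries the direction", {
  A <- seq(0.3, 2.5, length.out = 25)
  f <- fit_sigmoid(mk_mapping(A, F_S(A, c(10, -4, 1, 0.2))))
  expect_gt(coef(f)[["p4"]], 0)
  expect_lt(coef(f)[["p2"]], 0)    # decreasing mapping classified by sign
})

test_that("joint fit with a null phase term reduces to the amplitude sigmoid", {
  set.seed(7)
  n <- 8 * 16 * 250
  amp <- exp(rnorm(n, 0, 0.5)); amp <- amp / mean(amp)
  ph <- runif(n, -pi, pi)
  rate <- pmax(F_S(amp, c(22, -5, 1, 0.2)), 0)
  s <- rbinom(n, 1, rate / 1000)
  fb <- fit_beta_rate(joint_binning(amp, ph, s, 8, 16))
  expect_lt(abs(fb$w_AMP(1)), 0.6)          # phase term ~ 0
  uni <- fit_sigmoid(equal_count_binning(amp, s, 25))
  expect_equal(fb$R_AMP(1), predict(uni, 1), tolerance = 0.08)
  expect_equal(coef(fb)[["p2"]], coef(uni)[["p2"]], tolerance = 0.25)
  # phase-modulation depth at mean amplitude equals p5 + p6
  p <- coef(fb)
  expect_equal(fb$w_AMP(1), p[["p5"]] + p[["p6"]], tolerance = 1e-12)
})

test_that("Bernoulli-sampled mappings recover generator parameters", {
  set.seed(8)
  n <- 150000
  amp <- exp(rnorm(n, 0, 0.5)); amp <- amp / mean(amp)
  ph <- runif(n, -pi, pi)
  s <- rbinom(n, 1, pmax(20 + 5 * cos(ph - 1), 0) / 1000)
  fc <- fit_cosine({
    m <- equal_count_binning(ph, s, 25); m$variable <- "phase"; m
  })
  expect_equal(unname(coef(fc)), c(20, 5, 1), tolerance = 0.06)
  s2 <- rbinom(n, 1, pmax(F_D(ph, c(12, 2, 1.5, 0.5)), 0) / 1000)
  fd <- fit_vonmises_rate({
    m <- equal_count_binning(ph, s2, 25); m$variable <- "pd"; m
  })
  expect_equal(coef(fd)[["p4"]], 0.5, tolerance = 0.15)
  expect_equal(coef(fd)[["p3"]], 1.5, tolerance = 0.5)
})

test_that("fit objects expose the standard modelling methods", {
  A <- seq(0.3, 2.5, length.out = 25)
  m <- mk_mapping(A, F_S(A, c(10, -4, 1, 0.2)) + rnorm(25, 0, 0.1))
  f <- fit_sigmoid(m)
  expect_s3_class(f, "clc_fit")
  expect_length(coef(f), 4)
  expect_length(residuals(f), 25)
  expect_equal(predict(f), f$fitted)
  expect_output(print(f), "amplitude-to-rate")
  expect_output(print(summary(f)), "RSS")
  sims <- simulate(f, nsim = 2, seed = 1, newdata = runif(5000, 0.5, 2))
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "spike_train")
})
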