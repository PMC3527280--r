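# Random improper complex Gaussian samples with known structure.
rand_complex <- function(n, N, scale = NULL, improper = 0) {
  X <- matrix(complex(real = rnorm(n * N), imaginary = rnorm(n * N)), n, N)
  if (!is.null(scale)) X <- X %*% diag(scale, N)
  if (improper > 0) X <- X + improper * Conj(X)   # injects pseudo-covariance
  X
}

test_that("the fitted augmented mean is the sample mean, exactly", {
  set.seed(80)
  X <- rand_complex(500, 3) + 2 + 1i
  m <- fit_complex_gaussian(X)
  expect_identical(m$mu, colMeans(X))
})

test_that("pseudo-covariance of circular data shrinks with sample size", {
  set.seed(81)
  frob <- function(M) sqrt(sum(Mod(M)^2))
  norms <- vapply(c(200, 2000, 20000), function(n) {
    m <- fit_complex_gaussian(rand_complex(n, 4))
    frob(m$C) / frob(m$Gamma)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 0.05)
  # genuinely improper data keeps a large pseudo-covariance
  mi <- fit_complex_gaussian(rand_complex(20000, 4, improper = 0.5))
  expect_gt(frob(mi$C) / frob(mi$Gamma), 0.5)
})

test_that("zero shrinkage recovers the empirical augmented covariance exactly", {
  set.seed(85)
  X <- rand_complex(1000, 3, improper = 0.2)
  m <- fit_complex_gaussian(X, shrinkage = 0)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(m$Gamma, crossprod(Xc, Conj(Xc)) / 1000, tolerance = 1e-12)
  expect_equal(m$C, crossprod(Xc, Xc) / 1000, tolerance = 1e-12)
})

test_that("log-density agrees with the real 2N-Gaussian oracle to 1e-8", {
  set.seed(82)
  for (N in c(2, 5, 8)) {
    X <- rand_complex(4000, N, scale = seq(0.5, 2, length.out = N),
                      improper = 0.3)
    m <- fit_complex_gaussian(X, shrinkage = 1e-4)
    pts <- X[sample(4000, 100), , drop = FALSE]
    # oracle: generic real multivariate normal on [Re; Im], built from the
    # stacked real data directly (plus the model's diagonal shrinkage)
    Rr <- cbind(Re(X), Im(X))
    mu_r <- colMeans(Rr)
    S <- stats::cov(Rr) * (nrow(Rr) - 1) / nrow(Rr)
    # same diagonal ridge as the model, expressed through the real trace
    # (tr Gamma = tr S for the stacked representation)
    lam <- m$shrinkage * sum(diag(S)) / N
    S <- S + diag(lam / 2, 2 * N)
    ld <- determinant(S, logarithm = TRUE)$modulus
    Si <- solve(S)
    pr <- cbind(Re(pts), Im(pts))
    oracle <- vapply(seq_len(100), function(i) {
      d <- pr[i, ] - mu_r
      as.numeric(-N * log(2 * pi) - ld / 2 - d %*% Si %*% d / 2)
    }, numeric(1))
    expect_equal(cgauss_logdensity(m, pts), oracle, tolerance = 1e-8)
  }
})

test_that("log-density matches direct evaluation of the augmented complex form", {
  set.seed(83)
  N <- 3
  X <- rand_complex(2000, N, improper = 0.4)
  m <- fit_complex_gaussian(X)
  RB <- rbind(cbind(m$Gamma, m$C), cbind(Conj(m$C), Conj(m$Gamma)))
  ev <- eigen(RB, symmetric = TRUE, only.values = TRUE)$values
  pts <- X[1:50, , drop = FALSE]
  direct <- vapply(1:50, function(i) {
    xb <- c(pts[i, ] - m$mu, Conj(pts[i, ] - m$mu))
    Re(-N * log(pi) - sum(log(ev)) / 2 -
         Conj(xb) %*% solve(RB, xb) / 2)
  }, numeric(1))
  expect_equal(cgauss_logdensity(m, pts), direct, tolerance = 1e-8)
})

test_that("likelihood ratios vanish for identical models and obey the minus rule", {
  set.seed(84)
  X <- rand_complex(1000, 3)
  m <- fit_complex_gaussian(X)
  expect_equal(loglik_ratio_series(m, m, X), rep(0, 1000), tolerance = 1e-12)
  m2 <- fit_complex_gaussian(rand_complex(1000, 3, scale = c(2, 1, 0.5)))
  L <- loglik_ratio_series(m2, m, X)
  expect_equal(L, cgauss_logdensity(m2, X) - cgauss_logdensity(m, X),
               tolerance = 1e-12)
  m4 <- fit_complex_gaussian(rand_complex(1000, 4))
  expect_error(loglik_ratio_series(m4, m, X), "channel counts")
  expect_error(fit_complex_gaussian(rand_complex(20, 3)), "too few samples")
})

test_that("spike-triggered structure raises L at spike samples", {
  f <- fix_meso()
  arr <- fixture("mv_array", function()
    generate_array_lfp(fix_meso()$meso, "L", grid = electrode_grid(3),
                       seed = 90, cal_dur_s = 30, n_cal = 1))
  fa <- clcoupling:::filter_array(arr)
  gt <- unit_ground_truth("m",
    MC = unit_params(r_baseline = 20, amp = c(p2 = 8, p3 = 1, p4 = 0.2),
                     phase = c(b1 = 5, b2 = 0, pref = 1)),
    BC = unit_params())
  avg <- suppressWarnings(spatial_average(arr))   # 9-channel test array
  meso_a <- normalize_amplitude(filter_signal(avg, 28))
  s <- generate_spikes(gt, "MC", meso_a, seed = 91)
  mods <- fit_mv_clc(fa$Z[fa$valid, ], s$x[fa$valid])
  L <- loglik_ratio_series(mods$st, mods$base, fa$Z[fa$valid, ])
  sp <- s$x[fa$valid] == 1
  expect_gt(mean(L[sp]), mean(L[!sp]))
  # calibrated prediction on held-out half recovers the rate association
  half <- seq_len(floor(sum(fa$valid) / 2))
  pr <- calibrate_and_predict(L[half], s$x[fa$valid][half], L[-half])
  ev <- evaluate_prediction(pr, s$x[fa$valid][-half])
  expect_gt(ev$slope, 0.6)
  expect_gt(ev$r_squared, 0.5)
  # monotone prediction when the calibration slope is positive
  if (coef(pr$sigmoid)[["p2"]] > 0) {
    ord <- order(pr$L_test)
    expect_true(all(diff(pr$R_est[ord]) >= -1e-9))
  }
  # shuffled test spikes destroy the association
  set.seed(92)
  ev0 <- evaluate_prediction(pr, sample(s$x[fa$valid][-half]))
  expect_lt(abs(ev0$slope), 0.25)
  expect_error(evaluate_prediction(rep(3, 1000), rbinom(1000, 1, 0.02)),
               "degenerate")
})

test_that("an oracle predictor evaluates with slope near one", {
  f <- fix_meso()
  gt <- unit_ground_truth("o",
    MC = unit_params(r_baseline = 15, amp = c(p2 = 7, p3 = 1, p4 = 0.25)),
    BC = unit_params())
  s <- generate_spikes(gt, "MC", f$aL, seed = 93)
  rate <- true_rate_series(gt, "MC", f$aL)
  ev <- evaluate_prediction(rate[f$aL$valid], s$x[f$aL$valid])
  expect_equal(ev$slope, 1, tolerance = 0.1)
  # conservation of the evaluation binning
  m <- ev$mapping
  expect_equal(mean(m$R), sum(s$x[f$aL$valid][seq_len(m$N_t)]) * 1000 / m$N_t,
               tolerance = 1e-12)
})

test_that("channel subsets are nested and validated", {
  co <- electrode_grid(8)
  subs <- channel_subsets(co)
  expect_equal(vapply(subs, length, integer(1)),
               c(ch4 = 4L, ch16 = 16L, ch36 = 36L, ch64 = 64L))
  expect_true(all(subs$ch4 %in% subs$ch16))
  expect_true(all(subs$ch16 %in% subs$ch36))
  expect_true(all(subs$ch36 %in% subs$ch64))
})
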