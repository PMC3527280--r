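# Multivariate spike-rate prediction from multichannel complex beta
# coefficients.
#
# The baseline and spike-triggered distributions of the N-channel complex
# vector x are modeled as (possibly improper) complex Gaussians via the
# augmented representation x_B = [x; conj(x)]:
#   p(x) = beta * exp(-1/2 (x_B - mu_B)^H R_B^{-1} (x_B - mu_B)),
#   beta = 1 / (pi^N sqrt(det R_B)),
# with R_B = [[Gamma, C], [conj(C), conj(Gamma)]] built from the Hermitian
# covariance Gamma and the pseudo-covariance C.  Numerically, log-densities
# are evaluated through the equivalent 2N-dimensional real Gaussian of
# [Re x; Im x] (identical density value), using a Cholesky factorization of
# the real covariance.  Per-sample log-likelihood ratios
# L(x) = log p_ST(x) - log p_BASE(x) are calibrated to rates with the same
# equal-count binning + sigmoid machinery as the univariate mappings.

#' Fit a complex multivariate Gaussian (augmented form)
#'
#' @param X complex matrix, samples x channels.
#' @param shrinkage diagonal shrinkage weight `lambda`: the augmented
#'   covariance is regularized as `R_B + lambda * mean(diag(R_B)) * I`
#'   (spike-triggered sample counts can be small).
#' @return object of class `complex_gaussian`: `mu` (channel means),
#'   `Gamma`, `C`, the real-composite covariance `Sigma_r` with its
#'   Cholesky factor, and the log-normalizer.
#' @export
fit_complex_gaussian <- function(X, shrinkage = 1e-4) {
  X <- as.matrix(X)
  if (!is.complex(X)) X <- X + 0i
  if (any(!is.finite(Re(X))) || any(!is.finite(Im(X))))
    stop("non-finite inputs")
  n <- nrow(X); N <- ncol(X)
  if (n < 10 * N)
    stop("too few samples (", n, ") for ", N, " channels; need >= ", 10 * N)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Gamma <- crossprod(Xc, Conj(Xc)) / n     # E[z z^H]
  C <- crossprod(Xc, Xc) / n               # E[z z^T]
  lam <- shrinkage * Re(sum(diag(Gamma))) / N
  Gamma <- Gamma + diag(lam, N)
  # real composite covariance of [Re x; Im x]
  Sxx <- (Re(Gamma) + Re(C)) / 2
  Syy <- (Re(Gamma) - Re(C)) / 2
  Syx <- (Im(Gamma) + Im(C)) / 2
  Sxy <- (Im(C) - Im(Gamma)) / 2
  Sigma_r <- rbind(cbind(Sxx, Sxy), cbind(Syx, Syy))
  Sigma_r <- (Sigma_r + t(Sigma_r)) / 2
  Ch <- chol(Sigma_r)
  structure(list(mu = mu, Gamma = Gamma, C = C, Sigma_r = Sigma_r,
                 chol_r = Ch, logdet_r = 2 * sum(log(diag(Ch))),
                 N = N, n = n, shrinkage = shrinkage),
            class = "complex_gaussian")
}

# Frobenius norm of a complex matrix (base norm() discards Im parts).
cnorm <- function(M) sqrt(sum(Mod(M)^2))

#' @export
print.complex_gaussian <- function(x, ...) {
  cat("Complex Gaussian model: ", x$N, " channels, fitted on ", x$n,
      " samples (shrinkage ", x$shrinkage, ")\n  ||pseudo-covariance|| / ",
      "||covariance|| = ",
      signif(cnorm(x$C) / cnorm(x$Gamma), 3), "\n", sep = "")
  invisible(x)
}

#' Log-density of a complex Gaussian model
#'
#' Evaluated through the equivalent real 2N-dimensional Gaussian (the two
#' densities agree identically, including normalization).
#'
#' @param model a `complex_gaussian`.
#' @param X complex matrix, samples x channels.
#' @return numeric log-density per sample.
#' @export
cgauss_logdensity <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$N) stop("channel count mismatch")
  Xc <- sweep(X, 2, model$mu)
  Rr <- cbind(Re(Xc), Im(Xc))
  Q <- backsolve(model$chol_r, t(Rr), transpose = TRUE)
  -model$N * log(2 * pi) - model$logdet_r / 2 - colSums(Q^2) / 2
}

#' Log-likelihood ratio series between two complex Gaussian models
#'
#' @param model_st spike-triggered model.
#' @param model_base baseline model.
#' @param X complex matrix of filtered multichannel samples.
#' @return numeric `L = log p_ST - log p_BASE` per sample, finite on finite
#'   inputs.
#' @export
loglik_ratio_series <- function(model_st, model_base, X) {
  if (model_st$N != model_base$N) stop("models have different channel counts")
  cgauss_logdensity(model_st, X) - cgauss_logdensity(model_base, X)
}

#' Fit baseline and spike-triggered complex Gaussian models
#'
#' The baseline model uses all (valid) samples; the spike-triggered model
#' the samples at the spikes' 1-ms bins.
#'
#' @param X complex matrix, samples x channels (filtered, per-channel
#'   amplitude-normalized).
#' @param spikes [spike_train()] or binary vector aligned with rows of `X`.
#' @param valid optional logical row mask.
#' @param shrinkage passed to [fit_complex_gaussian()].
#' @return list with `base` and `st` models.
#' @export
fit_mv_clc <- function(X, spikes, valid = NULL, shrinkage = 1e-4) {
  s <- as_spike_vector(spikes)
  stopifnot(nrow(X) == length(s))
  if (is.null(valid)) valid <- rep(TRUE, length(s))
  list(base = fit_complex_gaussian(X[valid, , drop = FALSE], shrinkage),
       st = fit_complex_gaussian(X[valid & s == 1L, , drop = FALSE],
                                 shrinkage))
}

#' Calibrate the L-to-rate mapping and predict rates on test data
#'
#' Equal-count bins the training log-likelihood ratio against the spike
#' train, fits the 4-parameter sigmoid `F_S(L)`, and applies it to the test
#' series.
#'
#' @param L_train,L_test numeric log-likelihood-ratio series.
#' @param spikes_train training [spike_train()] or binary vector.
#' @param n_bins equal-count bins for the calibration.
#' @param fs sampling rate in Hz.
#' @return object of class `rate_prediction`: the calibration `sigmoid`
#'   fit, predicted test rates `R_est` (clipped at 0), and `L_test`.
#' @export
calibrate_and_predict <- function(L_train, spikes_train, L_test,
                                  n_bins = 25, fs = 1000) {
  m <- equal_count_binning(L_train, spikes_train, n_bins = n_bins, fs = fs)
  m$variable <- "log-likelihood ratio"
  sig <- fit_sigmoid(m)
  structure(list(sigmoid = sig, L_test = L_test,
                 R_est = pmax(predict(sig, L_test), 0), fs = fs),
            class = "rate_prediction")
}

#' @export
print.rate_prediction <- function(x, ...) {
  cat("L-to-rate prediction: R_est in [", signif(min(x$R_est), 4), ", ",
      signif(max(x$R_est), 4), "] spikes/s over ", length(x$R_est),
      " samples\n", sep = "")
  invisible(x)
}

#' Evaluate predicted against measured rates
#'
#' Equal-count bins the predicted rate series, computes the measured rate
#' per bin, and summarizes with the least-squares line of measured on
#' predicted rate.
#'
#' @param prediction a `rate_prediction` (or numeric predicted-rate series).
#' @param spikes_test test [spike_train()] or binary vector.
#' @param n_bins evaluation bins.
#' @param fs sampling rate in Hz.
#' @return object of class `prediction_evaluation`: the evaluation
#'   `mapping` (a `binned_mapping` of measured rate on predicted-rate
#'   support), `slope`, `r_squared`, and `rate_range` (measured).
#' @export
evaluate_prediction <- function(prediction, spikes_test, n_bins = 25,
                                fs = 1000) {
  R_est <- if (inherits(prediction, "rate_prediction")) prediction$R_est
           else as.numeric(prediction)
  if (stats::sd(R_est) < 1e-12)
    stop("degenerate (constant) predicted-rate series")
  m <- equal_count_binning(R_est, spikes_test, n_bins = n_bins, fs = fs)
  m$variable <- "predicted rate"
  fit <- stats::lm(m$R ~ m$A)
  structure(list(mapping = m, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 rate_range = diff(range(m$R))),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat("Estimated-to-measured rate evaluation: slope ", signif(x$slope, 4),
      ", r^2 = ", signif(x$r_squared, 4), ", measured-rate range ",
      signif(x$rate_range, 4), " spikes/s\n", sep = "")
  invisible(x)
}

# Filter + normalize all array channels at the beta frequency, returning
# the complex matrix and the common validity mask.
filter_array <- function(array, v0 = NULL, s0 = NULL) {
  stopifnot(inherits(array, "lfp_array"))
  if (is.null(v0)) v0 <- array$f0
  Z <- NULL; valid <- NULL
  for (c_ in seq_len(ncol(array$lfp))) {
    a <- normalize_amplitude(filter_signal(array$lfp[, c_], v0, s0, array$fs))
    if (is.null(Z)) { Z <- matrix(0i, length(a$z), ncol(array$lfp)); valid <- a$valid }
    Z[, c_] <- a$z
  }
  list(Z = Z, valid = valid)
}

#' Nested channel subsets around a seed electrode
#'
#' Square blocks of 4, 16, 36 and 64 electrodes anchored at the corner
#' closest to the seed channel's grid position.
#'
#' @param coords channel coordinates (mm), as in an `lfp_array`.
#' @param sizes block sizes (channel counts; perfect squares).
#' @return named list of channel index vectors.
#' @export
channel_subsets <- function(coords, sizes = c(4, 16, 36, 64)) {
  ux <- sort(unique(coords[, 1])); uy <- sort(unique(coords[, 2]))
  lapply(stats::setNames(sizes, paste0("ch", sizes)), function(sz) {
    k <- as.integer(round(sqrt(sz)))
    stopifnot(k * k == sz, k <= length(ux))
    which(coords[, 1] %in% ux[seq_len(k)] & coords[, 2] %in% uy[seq_len(k)])
  })
}

#' Prediction performance as a function of channel-subset size
#'
#' Runs the full multivariate pipeline (model fits on training samples,
#' L-to-rate calibration, evaluation on held-out samples) for nested
#' channel subsets; training and test samples are split by trial parity.
#'
#' @param array an `lfp_array`.
#' @param spikes [spike_train()] or binary vector.
#' @param trials `trial_table` defining the parity split.
#' @param subsets named list of channel index vectors, see
#'   [channel_subsets()].
#' @param v0,s0 filter parameters (default: the array's beta peak).
#' @param shrinkage,n_bins passed through.
#' @return data.frame with one row per subset: `n_channels`, `slope`,
#'   `r_squared`, `rate_range`.
#' @export
channel_subset_analysis <- function(array, spikes, trials,
                                    subsets = channel_subsets(array$coords),
                                    v0 = NULL, s0 = NULL, shrinkage = 1e-4,
                                    n_bins = 25) {
  fa <- filter_array(array, v0, s0)
  s <- as_spike_vector(spikes)
  id <- sample_trial_id(trials, length(s))
  train <- fa$valid & id %% 2L == 1L & id > 0L
  test <- fa$valid & id %% 2L == 0L & id > 0L
  rows <- lapply(names(subsets), function(nm) {
    ch <- subsets[[nm]]
    if (length(ch) == 0) stop("empty channel subset '", nm, "'")
    if (any(ch > ncol(fa$Z))) stop("subset '", nm, "' not within the array")
    Zs <- fa$Z[, ch, drop = FALSE]
    mods <- fit_mv_clc(Zs[train, , drop = FALSE], s[train],
                       shrinkage = shrinkage)
    Ltr <- loglik_ratio_series(mods$st, mods$base, Zs[train, , drop = FALSE])
    Lte <- loglik_ratio_series(mods$st, mods$base, Zs[test, , drop = FALSE])
    pr <- calibrate_and_predict(Ltr, s[train], Lte, n_bins = n_bins)
    ev <- evaluate_prediction(pr, s[test], n_bins = n_bins)
    data.frame(subset = nm, n_channels = length(ch), slope = ev$slope,
               r_squared = ev$r_squared, rate_range = ev$rate_range)
  })
  do.call(rbind, rows)
}

#' Within- versus cross-task prediction transfer
#'
#' Fits the multivariate model on one task's training half and evaluates
#' on the held-out half of the same task (within) and of the other task
#' (cross), for all four train/test combinations.
#'
#' @param data_MC,data_BC lists with elements `Z` (complex samples x
#'   channels), `spikes`, `trials`, and optional `valid`.
#' @param shrinkage,n_bins passed through.
#' @return data.frame with rows `BC->BC`, `BC->MC`, `MC->MC`, `MC->BC`:
#'   `slope`, `r_squared`, `rate_range`.
#' @export
cross_task_transfer <- function(data_MC, data_BC, shrinkage = 1e-4,
                                n_bins = 25) {
  prep <- function(d) {
    s <- as_spike_vector(d$spikes)
    v <- d$valid %||% rep(TRUE, length(s))
    id <- sample_trial_id(d$trials, length(s))
    list(Z = d$Z, s = s, train = v & id %% 2L == 1L,
         test = v & id %% 2L == 0L & id > 0L)
  }
  dd <- list(MC = prep(data_MC), BC = prep(data_BC))
  combos <- expand.grid(train = c("BC", "MC"), test = c("BC", "MC"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- dd[[combos$train[i]]]; te <- dd[[combos$test[i]]]
    mods <- fit_mv_clc(tr$Z[tr$train, , drop = FALSE], tr$s[tr$train],
                       shrinkage = shrinkage)
    Ltr <- loglik_ratio_series(mods$st, mods$base, tr$Z[tr$train, , drop = FALSE])
    Lte <- loglik_ratio_series(mods$st, mods$base, te$Z[te$test, , drop = FALSE])
    pr <- calibrate_and_predict(Ltr, tr$s[tr$train], Lte, n_bins = n_bins)
    ev <- evaluate_prediction(pr, te$s[te$test], n_bins = n_bins)
    data.frame(train = combos$train[i], test = combos$test[i],
               within = combos$train[i] == combos$test[i],
               slope = ev$slope, r_squared = ev$r_squared,
               rate_range = ev$rate_range)
  })
  do.call(rbind, rows)
}
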