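# Within-task stability, cross-task remapping, conditioning, frequency
# profiles, and the external (trial/target) tuning model.

# Per-sample trial membership: 0 outside trials, otherwise the trial_id.
sample_trial_id <- function(trials, n) {
  id <- integer(n)
  for (i in seq_len(nrow(trials))) {
    a <- max(1L, trials$t_center_on[i] + 1L)
    b <- min(n, trials$t_reward_off[i])
    if (a > n) break
    id[a:b] <- trials$trial_id[i]
  }
  id
}

# Trial-stage windows (documented boundaries): move-to-center = center cue
# onset to center entry; move-to-target = go cue to target entry; reward =
# reward on to reward off.
stage_windows <- function(trials, stage) {
  switch(stage,
         "move_to_center" = cbind(trials$t_center_on, trials$t_center_enter),
         "move_to_target" = cbind(trials$t_go, trials$t_target_enter),
         "reward"         = cbind(trials$t_reward_on, trials$t_reward_off),
         stop("unknown trial stage '", stage, "'"))
}

windows_to_mask <- function(w, n) {
  m <- logical(n)
  for (i in seq_len(nrow(w))) {
    a <- max(1L, w[i, 1] + 1L); b <- min(n, w[i, 2])
    if (a <= b) m[a:b] <- TRUE
  }
  m
}

#' Split-half fits of a CLC mapping
#'
#' Partitions samples by trial parity (odd vs even trials) and fits the
#' requested mapping independently on each half.
#'
#' @param analytic normalized `analytic_signal` (or numeric series for
#'   `what = "phase_difference"`).
#' @param spikes [spike_train()] or binary vector.
#' @param trials `trial_table` defining the parity partition (>= 2 trials);
#'   samples outside trials are excluded.
#' @param what which mapping to fit, see [clc_fit()].
#' @param n_bins bins per half.
#' @return list with elements `half1` (odd trials) and `half2` (even
#'   trials), each a fitted `clc_fit`.
#' @export
split_half_fits <- function(analytic, spikes, trials,
                            what = c("amplitude", "phase"), n_bins = 25) {
  what <- match.arg(what)
  stopifnot(nrow(trials) >= 2)
  x <- switch(what, amplitude = clc_amplitude(analytic),
              phase = clc_phase(analytic))
  s <- as_spike_vector(spikes)
  id <- sample_trial_id(trials, length(x))
  base_valid <- analytic$valid & id > 0L
  fit_half <- function(par) {
    v <- base_valid & (id %% 2L == par)
    if (!any(v)) stop("empty split half (parity ", par, ")")
    m <- equal_count_binning(x, s, n_bins = n_bins, fs = analytic$fs, valid = v)
    m$variable <- what
    if (what == "amplitude") fit_sigmoid(m) else fit_cosine(m)
  }
  list(half1 = fit_half(1L), half2 = fit_half(0L))
}

#' Split-half and cross-task parameter comparison for an ensemble
#'
#' Fits the chosen mapping on odd/even trial halves of two task datasets
#' for every unit, then reports within-task (BC1/BC2, MC1/MC2) and
#' cross-task (BC x MC) correlations of the fitted parameters across the
#' ensemble.
#'
#' @param datasets named list with elements `MC` and `BC`, each a list with
#'   `analytic` (normalized `analytic_signal`), `spikes` (list of spike
#'   trains, same units in the same order), `trials`.
#' @param what mapping family (`"amplitude"` or `"phase"`).
#' @param param what to correlate across units: `"rate_change"` (default
#'   for amplitude) is the signed fitted rate change between amplitudes 0.6
#'   and 1.6 — the stable direction-and-slope summary of the mapping; a
#'   coefficient index selects a raw parameter instead (the preferred phase
#'   p3, compared with circular correlation, is the default for phase).
#' @param n_bins bins per fit.
#' @return object of class `split_half_comparison`: per-unit parameter
#'   table and a correlation summary with `within` (mean of BC1:BC2 and
#'   MC1:MC2) and `cross` (mean over the four BC x MC pairings).
#' @export
split_half_compare <- function(datasets, what = c("amplitude", "phase"),
                               param = NULL, n_bins = 25) {
  what <- match.arg(what)
  stopifnot(all(c("MC", "BC") %in% names(datasets)))
  if (is.null(param)) param <- if (what == "amplitude") "rate_change" else 3L
  extract <- function(fit) {
    if (identical(param, "rate_change"))
      diff(predict(fit, c(0.6, 1.6)))
    else stats::coef(fit)[[param]]
  }
  per_task <- lapply(datasets[c("BC", "MC")], function(d) {
    halves <- lapply(d$spikes, function(s)
      split_half_fits(d$analytic, s, d$trials, what, n_bins))
    list(h1 = vapply(halves, function(h) extract(h$half1), numeric(1)),
         h2 = vapply(halves, function(h) extract(h$half2), numeric(1)))
  })
  cc <- if (what == "phase" && identical(param, 3L)) circ_cor else stats::cor
  pairs <- list(BC1_BC2 = cc(per_task$BC$h1, per_task$BC$h2),
                MC1_MC2 = cc(per_task$MC$h1, per_task$MC$h2),
                BC1_MC1 = cc(per_task$BC$h1, per_task$MC$h1),
                BC1_MC2 = cc(per_task$BC$h1, per_task$MC$h2),
                BC2_MC1 = cc(per_task$BC$h2, per_task$MC$h1),
                BC2_MC2 = cc(per_task$BC$h2, per_task$MC$h2))
  structure(list(parameters = per_task, correlations = unlist(pairs),
                 within = mean(unlist(pairs[1:2])),
                 cross = mean(unlist(pairs[3:6])),
                 what = what, param = param),
            class = "split_half_comparison")
}

#' @export
print.split_half_comparison <- function(x, ...) {
  cat("Split-half parameter stability (", x$what, ", parameter p", x$param,
      ")\n  within-task correlation: ", signif(x$within, 3),
      "\n  cross-task correlation:  ", signif(x$cross, 3), "\n", sep = "")
  print(signif(x$correlations, 3))
  invisible(x)
}

#' Condition a CLC mapping on target, trial stage, or amplitude quartile
#'
#' Restricts samples to each level of the condition and fits the requested
#' mapping per level.  Amplitude quartiles use an equal-count split of the
#' valid amplitude samples (0-25, 25-50, 50-75, 75-100 percentiles).
#'
#' @param analytic normalized `analytic_signal`.
#' @param spikes [spike_train()] or binary vector.
#' @param trials `trial_table` (needed for `target` and `stage`).
#' @param condition conditioning scheme.
#' @param what mapping family per level (`"amplitude"` or `"phase"`).
#' @param n_bins bins per level.
#' @return named list of fitted `clc_fit` objects (one per level).
#' @export
conditional_mapping <- function(analytic, spikes, trials = NULL,
                                condition = c("target", "stage",
                                              "amplitude_quartile"),
                                what = c("phase", "amplitude"), n_bins = 16) {
  condition <- match.arg(condition)
  what <- match.arg(what)
  x <- switch(what, amplitude = clc_amplitude(analytic),
              phase = clc_phase(analytic))
  s <- as_spike_vector(spikes)
  n <- length(x)
  amp <- clc_amplitude(analytic)
  masks <- switch(condition,
    target = {
      stopifnot(!is.null(trials))
      ann <- trial_annotation(trials, n)
      stats::setNames(lapply(1:8, function(k) ann$target == k),
                      paste0("target", 1:8))
    },
    stage = {
      stopifnot(!is.null(trials))
      stats::setNames(lapply(c("move_to_center", "move_to_target", "reward"),
                             function(st)
                               windows_to_mask(stage_windows(trials, st), n)),
                      c("move_to_center", "move_to_target", "reward"))
    },
    amplitude_quartile = {
      q <- stats::quantile(amp[analytic$valid], c(0.25, 0.5, 0.75))
      cuts <- c(-Inf, q, Inf)
      stats::setNames(lapply(1:4, function(k)
        amp > cuts[k] & amp <= cuts[k + 1]), paste0("q", 1:4))
    })
  lapply(masks, function(m) {
    v <- m & analytic$valid
    if (!any(v)) stop("empty condition: no samples in this level")
    bm <- equal_count_binning(x, s, n_bins = n_bins, fs = analytic$fs,
                              valid = v)
    bm$variable <- what
    if (what == "amplitude") fit_sigmoid(bm) else fit_cosine(bm)
  })
}

#' Frequency profiles of the amplitude- and phase-to-rate mappings
#'
#' For each center frequency of a bank: filter, normalize, fit the
#' amplitude (sigmoid) and phase (cosine) mappings, and report the
#' rate-change range of each fitted curve over its observed support.  Fit
#' failures are recorded per frequency rather than propagated.
#'
#' @param signal real-valued meso signal.
#' @param spikes [spike_train()] or binary vector.
#' @param bank data.frame with `v0`, `s0` (see [frequency_bank()]); all
#'   frequencies must be below Nyquist.
#' @param fs sampling rate in Hz.
#' @param n_bins bins per mapping.
#' @return data.frame with `v0`, `amp_range`, `phase_range` (spikes/s;
#'   `NA` where a fit failed) of class `frequency_profile`.
#' @export
frequency_profile <- function(signal, spikes, bank = frequency_bank(),
                              fs = 1000, n_bins = 25) {
  stopifnot(all(bank$v0 < fs / 2))
  s <- as_spike_vector(spikes)
  rows <- lapply(seq_len(nrow(bank)), function(i) {
    out <- data.frame(v0 = bank$v0[i], amp_range = NA_real_,
                      phase_range = NA_real_)
    a <- tryCatch(normalize_amplitude(filter_signal(signal, bank$v0[i],
                                                    bank$s0[i], fs)),
                  error = function(e) NULL)
    if (is.null(a)) return(out)
    fa <- tryCatch(clc_fit(a, s, "amplitude", n_bins = n_bins),
                   error = function(e) NULL)
    if (!is.null(fa)) {
      sup <- range(fa$mapping$A)
      out$amp_range <- abs(diff(predict(fa, sup)))
    }
    fp <- tryCatch(clc_fit(a, s, "phase", n_bins = n_bins),
                   error = function(e) NULL)
    if (!is.null(fp)) out$phase_range <- 2 * stats::coef(fp)[[2]]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frequency_profile", "data.frame")
  out
}

#' External tuning model: baseline, trial-stage, and target components
#'
#' Learns `r_baseline` (global mean rate), `r_trial` (go-cue-locked PSTH
#' deviation from baseline) and `r_target` (per-target mean deviation after
#' removing baseline and trial components) from training data; `predict()`
#' composes the components into an instantaneous rate series for novel
#' trials.
#'
#' @param spikes [spike_train()] or binary vector.
#' @param trials `trial_table`.
#' @param window go-cue-locked window in ms for the trial component.
#' @param bin_ms PSTH bin width in ms.
#' @param fs sampling rate in Hz.
#' @return object of class `external_tuning` with components `r_baseline`
#'   (spikes/s), `r_trial` (data.frame `time`, `rate`), `r_target`
#'   (length-8 deviations).
#' @export
external_tuning <- function(spikes, trials, window = c(-1000, 4000),
                            bin_ms = 200, fs = 1000) {
  s <- as_spike_vector(spikes)
  stopifnot(!is.null(trials))
  n <- length(s)
  r_baseline <- mean(s) * fs
  ev <- event_locked_average(s, trials$t_go, window, fs, as_rate = TRUE)
  nb <- length(ev$mean) %/% (bin_ms * fs / 1000)
  binid <- rep(seq_len(nb), each = bin_ms * fs / 1000,
               length.out = length(ev$mean))
  r_trial <- data.frame(
    time = as.numeric(tapply(ev$time, binid, mean)),
    rate = as.numeric(tapply(ev$mean, binid, mean)) - r_baseline)
  # target deviations, after removing baseline + trial components
  pred_bt <- predict_trial_component(r_trial, trials, n, fs, window) + r_baseline
  ann <- trial_annotation(trials, n)
  r_target <- vapply(1:8, function(k) {
    m <- ann$target == k
    if (!any(m)) return(0)
    mean(s[m]) * fs - mean(pred_bt[m])
  }, numeric(1))
  structure(list(r_baseline = r_baseline, r_trial = r_trial,
                 r_target = r_target, window = window, fs = fs),
            class = "external_tuning")
}

predict_trial_component <- function(r_trial, trials, n, fs, window) {
  out <- numeric(n)
  bin_ms <- diff(r_trial$time[1:2])
  for (i in seq_len(nrow(trials))) {
    rel0 <- round(trials$t_go[i] + r_trial$time - bin_ms / 2)
    for (b in seq_along(rel0)) {
      a <- max(1L, rel0[b] + 1L)
      bnd <- min(n, rel0[b] + bin_ms)
      if (a <= bnd) out[a:bnd] <- r_trial$rate[b]
    }
  }
  out
}

#' @export
predict.external_tuning <- function(object, trials, n, ...) {
  ann <- trial_annotation(trials, n)
  tgt <- numeric(n)
  m <- ann$target > 0
  tgt[m] <- object$r_target[ann$target[m]]
  pmax(object$r_baseline +
         predict_trial_component(object$r_trial, trials, n, object$fs,
                                 object$window) + tgt, 0)
}

#' @export
print.external_tuning <- function(x, ...) {
  cat("External tuning: baseline ", signif(x$r_baseline, 4),
      " spikes/s; trial component range [",
      signif(min(x$r_trial$rate), 3), ", ", signif(max(x$r_trial$rate), 3),
      "]; target deviations [", signif(min(x$r_target), 3), ", ",
      signif(max(x$r_target), 3), "]\n", sep = "")
  invisible(x)
}
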