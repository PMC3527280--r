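# Event-related averaging: ERPs, PSTHs, time-frequency maps, and
# movement-duration-sorted single-trial maps.

#' Event-locked average of a series
#'
#' Extracts epochs around event timestamps and averages across them.  Works
#' for raw voltages (ERP), normalized amplitude series (event-related
#' amplitude modulation) and binary spike vectors (multiply by `fs` for a
#' PSTH in spikes/s via `as_rate`).
#'
#' @param series numeric vector (or `analytic_signal`, whose amplitude is
#'   used with its mask).
#' @param events event timestamps in ms (epoch time 0).
#' @param window `c(lo, hi)` epoch window in ms relative to the event.
#' @param fs sampling rate in Hz.
#' @param as_rate multiply the mean by `fs` (for spike vectors).
#' @param mask optional logical validity mask; masked samples are dropped
#'   from the average sample-wise.
#' @return object of class `event_average`: `time` (ms), `mean`, `n_events`.
#' @export
event_locked_average <- function(series, events, window = c(-1000, 10000),
                                 fs = 1000, as_rate = FALSE, mask = NULL) {
  if (inherits(series, "analytic_signal")) {
    if (is.null(mask)) mask <- series$valid
    fs <- series$fs
    series <- clc_amplitude(series)
  }
  n <- length(series)
  lo <- round(window[1] * fs / 1000); hi <- round(window[2] * fs / 1000)
  idx0 <- round(events * fs / 1000)
  ok <- idx0 + lo >= 1 & idx0 + hi <= n
  if (any(!ok)) warning(sum(!ok), " event(s) with windows outside the recording dropped")
  idx0 <- idx0[ok]
  if (length(idx0) == 0) stop("zero usable events")
  rel <- lo:hi
  M <- vapply(idx0, function(i) series[i + rel], numeric(length(rel)))
  if (!is.null(mask)) {
    W <- vapply(idx0, function(i) as.numeric(mask[i + rel]), numeric(length(rel)))
    mu <- rowSums(M * W) / rowSums(W)
  } else mu <- rowMeans(M)
  if (as_rate) mu <- mu * fs
  structure(list(time = rel * 1000 / fs, mean = mu, n_events = length(idx0)),
            class = "event_average")
}

#' @export
print.event_average <- function(x, ...) {
  cat("Event-locked average over ", x$n_events, " events, ",
      x$time[1], "..", x$time[length(x$time)], " ms\n", sep = "")
  invisible(x)
}

#' @export
plot.event_average <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "l", xlab = "time from event (ms)",
                 ylab = "mean", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Event-locked time-frequency amplitude map
#'
#' Filters the signal at each center frequency of a bank, normalizes each
#' amplitude series to a grand mean of 1 (so map values are relative
#' modulations), and averages epochs around the events.
#'
#' @param signal real-valued series.
#' @param events event timestamps in ms.
#' @param bank data.frame with `v0`, `s0` columns, see [frequency_bank()].
#' @param window epoch window in ms.
#' @param fs sampling rate in Hz.
#' @return object of class `tf_map`: `time` (ms), `freq` (Hz), and the
#'   frequencies x time `map` matrix of relative amplitude.
#' @export
event_locked_tf <- function(signal, events, bank = frequency_bank(),
                            window = c(-1000, 10000), fs = 1000) {
  rows <- lapply(seq_len(nrow(bank)), function(i) {
    a <- normalize_amplitude(filter_signal(signal, bank$v0[i], bank$s0[i], fs))
    event_locked_average(a, events, window, fs)
  })
  structure(list(time = rows[[1]]$time, freq = bank$v0,
                 map = do.call(rbind, lapply(rows, `[[`, "mean"))),
            class = "tf_map")
}

#' @export
plot.tf_map <- function(x, ...) {
  graphics::image(x$time, seq_along(x$freq), t(x$map),
                  xlab = "time from event (ms)", ylab = "frequency index",
                  ...)
  invisible(x)
}

#' Movement-duration-sorted single-trial map
#'
#' Sorts trials by movement duration and applies a sliding-window average
#' over the sorted trials, aligned to the go cue.
#'
#' @param series numeric series (typically a normalized beta amplitude) or
#'   `analytic_signal`.
#' @param trials a `trial_table`.
#' @param window_trials sliding-window width in trials.
#' @param window epoch window in ms relative to the go cue.
#' @param fs sampling rate in Hz.
#' @return object of class `rt_map`: `time`, matrix `map` (one row per
#'   window position, in order of increasing movement duration), and the
#'   sorted durations.
#' @export
rt_sorted_map <- function(series, trials, window_trials = 250,
                          window = c(-1000, 10000), fs = 1000) {
  if (inherits(series, "analytic_signal")) {
    fs <- series$fs
    series <- clc_amplitude(series)
  }
  n_tr <- nrow(trials)
  if (n_tr < window_trials)
    stop("need at least ", window_trials, " trials, got ", n_tr)
  ord <- order(trials$movement_duration)
  lo <- round(window[1] * fs / 1000); hi <- round(window[2] * fs / 1000)
  rel <- lo:hi
  idx0 <- round(trials$t_go[ord] * fs / 1000)
  stopifnot(all(idx0 + lo >= 1), all(idx0 + hi <= length(series)))
  E <- vapply(idx0, function(i) series[i + rel], numeric(length(rel)))
  n_row <- n_tr - window_trials + 1L
  map <- matrix(0, n_row, length(rel))
  run <- rowSums(E[, seq_len(window_trials), drop = FALSE])
  map[1, ] <- run / window_trials
  if (n_row > 1) for (r in 2:n_row) {
    run <- run - E[, r - 1L] + E[, r + window_trials - 1L]
    map[r, ] <- run / window_trials
  }
  structure(list(time = rel * 1000 / fs, map = map,
                 sorted_duration = sort(trials$movement_duration),
                 window_trials = window_trials),
            class = "rt_map")
}

#' @export
print.rt_map <- function(x, ...) {
  cat("RT-sorted map: ", nrow(x$map), " sliding positions (window ",
      x$window_trials, " trials) x ", length(x$time), " samples\n", sep = "")
  invisible(x)
}
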