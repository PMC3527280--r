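# Plain-text interchange formats: CSV for trials, spikes, LFP matrices and
# binned mappings; JSON for ground truth, fitted parameters and model
# records.

#' Read and write trial tables
#'
#' @param trials a `trial_table`.
#' @param path CSV file path.
#' @return `read_trials()` returns a validated `trial_table`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  validate_trial_table(out)
  out
}

#' Read and write spike trains as (unit_id, time_ms) CSV
#'
#' @param spikes a [spike_train()] or list of them.
#' @param path CSV file path.
#' @param n recording length in samples (for reading).
#' @param fs sampling rate in Hz.
#' @return `read_spikes()` returns a named list of [spike_train()]s.
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  rows <- do.call(rbind, lapply(spikes, function(s)
    data.frame(unit_id = s$unit_id, time_ms = (which(s$x == 1L) - 1L) *
                 1000 / s$fs)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, n, fs = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df$time_ms, df$unit_id), function(tm)
    spike_train(n, unit_id = NA, fs = fs, times_ms = tm))
}

#' Read and write an LFP array as CSV plus a JSON sidecar
#'
#' The matrix is written channels x samples (one row per channel); the
#' sidecar records `fs`, `f0`, `hemisphere`, `grid_pitch_mm` and the
#' channel coordinates.
#'
#' @param array an `lfp_array`.
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return `read_lfp_array()` returns an `lfp_array`.
#' @export
write_lfp_array <- function(array, path) {
  utils::write.table(t(array$lfp), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = array$fs, f0 = array$f0,
                            hemisphere = array$hemisphere,
                            grid_pitch_mm = array$pitch_mm,
                            coords = array$coords),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lfp_array
#' @export
read_lfp_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  M <- t(as.matrix(utils::read.csv(path, header = FALSE)))
  dimnames(M) <- NULL
  structure(list(lfp = M, coords = meta$coords, fs = meta$fs, f0 = meta$f0,
                 hemisphere = meta$hemisphere, pitch_mm = meta$grid_pitch_mm,
                 calibration = NULL),
            class = "lfp_array")
}

#' Write a binned mapping as CSV
#'
#' Columns: support, rate, count.
#'
#' @param mapping a `binned_mapping`.
#' @param path CSV path.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.csv(data.frame(support = mapping$A, rate = mapping$R,
                              count = mapping$P), path, row.names = FALSE)
  invisible(path)
}

# Flatten a clc_fit into a JSON-ready record.
fit_record <- function(fit, unit = NA, task = NA, condition = NA,
                       p_value = NA) {
  list(unit = unit, task = task, condition = condition,
       family = fit$family, parameters = as.list(stats::coef(fit)),
       r_squared = fit$r_squared, p_value = p_value)
}

#' Write fit records to JSON
#'
#' @param records list of records from fitted mappings (unit, task,
#'   condition, parameters, p-value, goodness of fit).
#' @param path JSON path.
#' @export
write_fit_records <- function(records, path) {
  jsonlite::write_json(records, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
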