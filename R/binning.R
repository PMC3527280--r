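# Equal-count (adaptive) binning of spike rates on a conditioning series.
#
# The procedure follows the matrix recipe exactly: form the N x 2 matrix of
# conditioning values and spike indicators, truncate to the largest
# N_t = n_b * P <= N, stable-sort rows by the conditioning value, partition
# into n_b consecutive blocks of P samples, and report the per-bin mean
# conditioning value A and spike rate R = (S_R / P) * (spikes in bin).
# Every bin holds exactly P samples, so the count-weighted mean of bin rates
# equals the truncated-data global rate exactly (conservation).

#' Equal-count binned rate mapping
#'
#' @param x conditioning series: numeric vector, or an `analytic_signal`
#'   (its amplitude is used).  Masked (invalid) samples are removed from
#'   both series before binning when a mask is available.
#' @param spikes a [spike_train()] or binary vector of the same length.
#' @param n_bins number of equal-count bins (>= 2).
#' @param fs sampling rate in Hz (taken from `spikes`/`x` when available).
#' @param valid optional logical mask overriding the analytic signal's.
#' @return object of class `binned_mapping`: list with bin supports `A`,
#'   rates `R` (spikes/s), samples-per-bin `P`, truncated length `N_t`,
#'   original length `N`, `n_bins`, `fs`, and the conditioning variable
#'   name.
#' @examples
#' set.seed(1)
#' x <- rnorm(10000); s <- rbinom(10000, 1, 0.02)
#' m <- equal_count_binning(x, s, n_bins = 25)
#' weighted.mean(m$R, rep(m$P, m$n_bins)) * m$N_t / m$fs  # total spikes kept
#' @export
equal_count_binning <- function(x, spikes, n_bins = 25, fs = NULL,
                                valid = NULL) {
  varname <- if (inherits(x, "analytic_signal")) "amplitude" else
    deparse(substitute(x))[1]
  if (inherits(x, "analytic_signal")) {
    if (is.null(valid)) valid <- x$valid
    if (is.null(fs)) fs <- x$fs
    x <- clc_amplitude(x)
  }
  s <- as_spike_vector(spikes)
  if (is.null(fs)) fs <- if (inherits(spikes, "spike_train")) spikes$fs else 1000
  if (length(x) != length(s))
    stop("conditioning series and spike vector lengths differ (",
         length(x), " vs ", length(s), ")")
  if (!is.null(valid)) {
    x <- x[valid]
    s <- s[valid]
  }
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2)
  N <- length(x)
  P <- N %/% n_bins
  N_t <- P * n_bins
  if (P < 1) stop("too little data: ", N, " samples for ", n_bins, " bins")
  x <- x[seq_len(N_t)]
  s <- s[seq_len(N_t)]
  ord <- order(x)                      # stable radix/shell sort: ties by index
  bin <- rep(seq_len(n_bins), each = P)
  A <- as.numeric(tapply(x[ord], bin, mean))
  R <- as.numeric(tapply(s[ord], bin, sum)) * fs / P
  structure(list(variable = varname, A = A, R = R, n_bins = n_bins, P = P,
                 N = N, N_t = N_t, fs = fs,
                 order = ord, bin = bin),
            class = "binned_mapping")
}

#' @export
print.binned_mapping <- function(x, ...) {
  cat("Equal-count rate mapping on '", x$variable, "': ", x$n_bins,
      " bins x ", x$P, " samples (", x$N - x$N_t, " of ", x$N,
      " samples truncated)\n", sep = "")
  cat("  support [", signif(min(x$A), 4), ", ", signif(max(x$A), 4),
      "], rates [", signif(min(x$R), 4), ", ", signif(max(x$R), 4),
      "] spikes/s\n", sep = "")
  invisible(x)
}

#' @export
plot.binned_mapping <- function(x, ...) {
  graphics::plot(x$A, x$R, pch = 16, xlab = x$variable,
                 ylab = "spike rate (spikes/s)", ...)
  invisible(x)
}

# Generic equal-count conditioning of a continuous response on a series:
# sort by x, truncate, partition, per-bin means of x and y.  Shares the
# conservation property of the rate mapping.
equal_count_condition <- function(x, y, n_bins) {
  stopifnot(length(x) == length(y), n_bins >= 2)
  N <- length(x)
  P <- N %/% n_bins
  N_t <- P * n_bins
  x <- x[seq_len(N_t)]; y <- y[seq_len(N_t)]
  ord <- order(x)
  bin <- rep(seq_len(n_bins), each = P)
  list(support = as.numeric(tapply(x[ord], bin, mean)),
       mean = as.numeric(tapply(y[ord], bin, mean)),
       P = P, N_t = N_t,
       groups = split(ord, bin))
}

#' Joint amplitude x phase equal-count binning
#'
#' Two-stage partition: samples are truncated to the largest multiple of
#' `n_ab * n_pb`, sorted by amplitude into `n_ab` outer bins, and each
#' amplitude bin is sorted by phase into `n_pb` inner bins; per-cell spike
#' rates are reported.
#'
#' @param amp amplitude series (numeric or `analytic_signal`).
#' @param phase phase series in radians (defaults to the analytic signal's
#'   phase when `amp` is an `analytic_signal`).
#' @param spikes [spike_train()] or binary vector.
#' @param n_ab,n_pb number of amplitude and phase bins.
#' @param fs sampling rate in Hz.
#' @param valid optional logical mask.
#' @param min_count minimum samples per cell; fewer is an error.
#' @return object of class `joint_binning`: `rates` (`n_ab` x `n_pb`
#'   matrix, spikes/s), `amp_support` (length `n_ab`), `phase_support`
#'   (`n_ab` x `n_pb`), per-cell count `P`, and bookkeeping fields.
#' @export
joint_binning <- function(amp, phase = NULL, spikes, n_ab = 8, n_pb = 16,
                          fs = NULL, valid = NULL, min_count = 100) {
  if (inherits(amp, "analytic_signal")) {
    if (is.null(valid)) valid <- amp$valid
    if (is.null(fs)) fs <- amp$fs
    if (is.null(phase)) phase <- clc_phase(amp)
    amp <- clc_amplitude(amp)
  }
  s <- as_spike_vector(spikes)
  if (is.null(fs)) fs <- if (inherits(spikes, "spike_train")) spikes$fs else 1000
  stopifnot(length(amp) == length(s), length(phase) == length(s))
  if (!is.null(valid)) {
    amp <- amp[valid]; phase <- phase[valid]; s <- s[valid]
  }
  N <- length(amp)
  cell <- n_ab * n_pb
  P <- N %/% cell
  if (P < min_count)
    stop("insufficient samples per cell: ", P, " < ", min_count)
  N_t <- P * cell
  amp <- amp[seq_len(N_t)]; phase <- phase[seq_len(N_t)]; s <- s[seq_len(N_t)]
  oa <- order(amp)
  abin <- rep(seq_len(n_ab), each = P * n_pb)
  rates <- matrix(0, n_ab, n_pb)
  phase_support <- matrix(0, n_ab, n_pb)
  amp_support <- numeric(n_ab)
  for (i in seq_len(n_ab)) {
    idx <- oa[abin == i]
    amp_support[i] <- mean(amp[idx])
    op <- idx[order(phase[idx])]
    pbin <- rep(seq_len(n_pb), each = P)
    phase_support[i, ] <- tapply(phase[op], pbin, mean)
    rates[i, ] <- tapply(s[op], pbin, sum) * fs / P
  }
  structure(list(rates = rates, amp_support = amp_support,
                 phase_support = phase_support, P = P, N = N, N_t = N_t,
                 n_ab = n_ab, n_pb = n_pb, fs = fs),
            class = "joint_binning")
}

#' @export
print.joint_binning <- function(x, ...) {
  cat("Joint amplitude x phase rate matrix: ", x$n_ab, " x ", x$n_pb,
      " cells, ", x$P, " samples/cell\n", sep = "")
  invisible(x)
}
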