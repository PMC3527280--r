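# Randomized permutation test for dependence of spike rate on a
# conditioning series.
#
# The test statistic is the across-bin variance of the equal-count binned
# rates.  The null distribution is built by circular rotation of the spike
# vector by uniform random offsets of at least 1 s, which preserves the
# spike train's autocorrelation while destroying its alignment with the
# conditioning series.  p = (1 + #{null >= observed}) / (1 + n_perm).

#' Permutation test for a CLC rate mapping
#'
#' @param x conditioning series (numeric or `analytic_signal`; amplitude is
#'   used for the latter).
#' @param spikes [spike_train()] or binary vector.
#' @param n_perm number of circular rotations (>= 100).
#' @param n_bins equal-count bins for the statistic.
#' @param min_shift_s minimum rotation in seconds.
#' @param seed optional RNG seed.
#' @param fs sampling rate in Hz.
#' @param valid optional logical mask (defaults to the analytic signal's).
#' @return object of class `clc_permutation`: observed statistic, null
#'   sample, and `p.value`.
#' @export
permutation_test <- function(x, spikes, n_perm = 1000, n_bins = 25,
                             min_shift_s = 1, seed = NULL, fs = NULL,
                             valid = NULL) {
  if (inherits(x, "analytic_signal")) {
    if (is.null(valid)) valid <- x$valid
    if (is.null(fs)) fs <- x$fs
    x <- clc_amplitude(x)
  }
  s <- as_spike_vector(spikes)
  if (is.null(fs)) fs <- if (inherits(spikes, "spike_train")) spikes$fs else 1000
  stopifnot(length(x) == length(s), n_perm >= 100)
  if (!is.null(valid)) { x <- x[valid]; s <- s[valid] }
  if (sum(s) == 0) stop("spike train has zero spikes")
  N <- length(x)
  P <- N %/% n_bins
  N_t <- P * n_bins
  lo <- as.integer(min_shift_s * fs)
  if (N - 2L * lo <= 0) stop("series too short for the minimum rotation")
  # bin membership of each (original-index) sample after amplitude sorting
  ord <- order(x[seq_len(N_t)])
  binof <- integer(N)
  binof[ord] <- rep(seq_len(n_bins), each = P)
  stat_of <- function(idx) {
    b <- binof[idx]
    counts <- tabulate(b[b > 0L], n_bins)
    stats::var(counts * fs / P)
  }
  sp_idx <- which(s == 1L)
  observed <- stat_of(sp_idx)
  if (!is.null(seed)) set.seed(seed)
  offsets <- sample(seq(lo, N - lo), n_perm, replace = TRUE)
  null <- vapply(offsets, function(off)
    stat_of(((sp_idx - 1L + off) %% N) + 1L), numeric(1))
  structure(list(statistic = observed, null = null,
                 p.value = (1 + sum(null >= observed)) / (1 + n_perm),
                 n_perm = n_perm, n_bins = n_bins),
            class = "clc_permutation")
}

#' @export
print.clc_permutation <- function(x, ...) {
  cat("Circular-rotation permutation test: bin-rate variance = ",
      signif(x$statistic, 4), ", p = ", signif(x$p.value, 3),
      " (", x$n_perm, " rotations)\n", sep = "")
  invisible(x)
}
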