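# Ensemble-level consequences of the fitted mappings: sigmoid crossover
# points, amplitude-indexed rank-order states, preferred-phase timing, and
# first-spiker fractions within beta cycles.

#' Crossover points of two sigmoid amplitude-to-rate mappings
#'
#' Roots of `F_i - F_j` over an amplitude domain, located by sign changes
#' on a dense grid and refined by bisection; crossovers closer than `tol`
#' are merged.  An empty set is a valid result (no overlap of the two
#' mappings).
#'
#' @param fit_i,fit_j `sigmoid_fit` objects (or length-4 parameter vectors).
#' @param domain numeric `c(lo, hi)` amplitude range.
#' @param n_grid grid resolution before refinement.
#' @param tol deduplication tolerance in amplitude units.
#' @return object of class `crossover_set`: sorted numeric crossover
#'   amplitudes with attribute `max_gap` (largest `|F_i - F_j|` at the
#'   returned roots).
#' @export
sigmoid_crossovers <- function(fit_i, fit_j, domain = c(0.2, 3),
                               n_grid = 1e4, tol = 1e-4) {
  pi_ <- if (inherits(fit_i, "clc_fit")) stats::coef(fit_i) else fit_i
  pj_ <- if (inherits(fit_j, "clc_fit")) stats::coef(fit_j) else fit_j
  stopifnot(all(is.finite(domain)), domain[2] > domain[1])
  f <- function(a) F_S(a, pi_) - F_S(a, pj_)
  g <- seq(domain[1], domain[2], length.out = n_grid)
  v <- f(g)
  roots <- g[v == 0]
  sc <- which(v[-1] * v[-n_grid] < 0)
  for (i in sc)
    roots <- c(roots, stats::uniroot(f, c(g[i], g[i + 1]), tol = 1e-10)$root)
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > tol)]
  structure(roots, max_gap = if (length(roots)) max(abs(f(roots))) else 0,
            class = "crossover_set")
}

#' @export
print.crossover_set <- function(x, ...) {
  if (length(x) == 0) cat("No crossovers (mappings do not overlap)\n")
  else cat("Crossovers at amplitude:", paste(signif(unclass(x), 5),
                                             collapse = ", "), "\n")
  invisible(x)
}

#' Amplitude-indexed rank-order states of an ensemble
#'
#' Merges all pairwise crossovers of the fitted sigmoids into interval
#' boundaries over the amplitude domain and assigns to each interval the
#' permutation of units sorted by descending model rate at the interval
#' midpoint; identical adjacent states are collapsed.  Ties in rate are
#' broken by unit order (deterministic).
#'
#' @param fits named list of `sigmoid_fit` objects (>= 2 units).
#' @param domain amplitude range; defaults to `c(0.2, 3)`, roughly the
#'   1st-99th percentile of normalized beta amplitude.
#' @param tol crossover merge tolerance.
#' @return object of class `rank_order_states`: data.frame `states` with
#'   `interval_lo`, `interval_hi`, `permutation` (unit names, highest rate
#'   first, "/"-separated), the crossover vector, and `n_states`.
#' @export
rank_order_states <- function(fits, domain = c(0.2, 3), tol = 1e-4) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits))) names(fits) <- paste0("u", seq_along(fits))
  pars <- lapply(fits, function(f)
    if (inherits(f, "clc_fit")) stats::coef(f) else f)
  xo <- c()
  for (i in seq_along(pars)) for (j in seq_along(pars)) if (i < j)
    xo <- c(xo, as.numeric(sigmoid_crossovers(pars[[i]], pars[[j]], domain,
                                              tol = tol)))
  xo <- sort(xo)
  if (length(xo) > 1) {
    merged <- xo[c(TRUE, diff(xo) > tol)]
    if (length(merged) < length(xo))
      warning("crossover collision below resolution; merged")
    xo <- merged
  }
  bounds <- c(domain[1], xo, domain[2])
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  perm_at <- function(a) {
    r <- vapply(pars, function(p) F_S(a, p), numeric(1))
    paste(names(fits)[order(-r, seq_along(r))], collapse = "/")
  }
  perms <- vapply(mids, perm_at, character(1))
  keep <- c(TRUE, perms[-1] != perms[-length(perms)])
  lo <- bounds[-length(bounds)][keep]
  hi <- c(lo[-1], domain[2])
  structure(list(states = data.frame(interval_lo = lo, interval_hi = hi,
                                     permutation = perms[keep]),
                 crossovers = xo, n_states = sum(keep)),
            class = "rank_order_states")
}

#' @export
print.rank_order_states <- function(x, ...) {
  cat("Rank-order state sequence: ", x$n_states, " states over ",
      length(x$crossovers), " crossovers\n", sep = "")
  print(utils::head(x$states, 10))
  if (nrow(x$states) > 10) cat("  ...\n")
  invisible(x)
}

#' Convert a preferred phase to a lag within the beta cycle
#'
#' Most-probable spike time relative to the beta trough:
#' `lag = wrap(pref - theta_trough) / (2 pi) * (1000 / v0)` ms, with the
#' trough at +/-pi under the package's phase convention (phase 0 at the
#' oscillation peak).
#'
#' @param fit a `cosine_fit`, or the preferred phase in radians.
#' @param v0 center frequency in Hz.
#' @return lag in ms within `[0, 1000/v0)`.
#' @examples
#' preferred_phase_to_lag(pi, 28)          # at the trough: 0 ms
#' 1000 / 28                               # full cycle ~ 36 ms
#' @export
preferred_phase_to_lag <- function(fit, v0 = 28) {
  stopifnot(v0 > 0)
  p <- if (inherits(fit, "cosine_fit")) stats::coef(fit)[[3]] else fit
  ((p - pi) %% (2 * pi)) / (2 * pi) * (1000 / v0)
}

#' Ensemble timing table from cosine fits
#'
#' @param fits named list of `cosine_fit` objects.
#' @param v0 center frequency in Hz.
#' @return data.frame (`unit`, `preferred_phase`, `lag_ms`) sorted by lag.
#' @export
timing_table <- function(fits, v0 = 28) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("u", seq_along(fits))
  out <- data.frame(unit = names(fits),
                    preferred_phase = vapply(fits, function(f)
                      stats::coef(f)[[3]], numeric(1)),
                    lag_ms = vapply(fits, preferred_phase_to_lag,
                                    numeric(1), v0 = v0))
  out[order(out$lag_ms), , drop = FALSE]
}

# Beta cycle boundaries: trough-to-trough segmentation at the phase wraps
# of the meso analytic signal (phase falls from ~+pi to ~-pi at the trough).
cycle_boundaries <- function(analytic) {
  th <- clc_phase(analytic)
  which(diff(th) < -pi) + 1L
}

#' First-spiker fraction for a pair of units
#'
#' Segments the recording into beta cycles (trough to trough), keeps the
#' cycles where each unit fires exactly once, and reports the fraction of
#' those cycles in which unit `a` spikes before unit `b`.  Cycles where the
#' two spikes share a 1-ms bin are excluded and counted; cycles touching
#' masked samples are dropped.
#'
#' @param train_a,train_b [spike_train()] objects.
#' @param analytic the meso `analytic_signal` defining the cycles.
#' @param deciles if `TRUE`, also stratify by decile of the per-cycle mean
#'   amplitude.
#' @return object of class `first_spiker`: `fraction`, `n_cycles`
#'   (qualifying), `n_ties`, and optionally `per_decile` (data.frame
#'   `decile`, `fraction`, `n`).
#' @export
first_spiker_fraction <- function(train_a, train_b, analytic,
                                  deciles = FALSE) {
  sa <- as_spike_vector(train_a)
  sb <- as_spike_vector(train_b)
  n <- length(analytic$z)
  stopifnot(length(sa) == n, length(sb) == n)
  bnd <- cycle_boundaries(analytic)
  if (length(bnd) < 3) stop("too few cycles")
  starts <- bnd[-length(bnd)]
  ends <- bnd[-1] - 1L
  # drop cycles overlapping masked samples
  ok <- analytic$valid[starts] & analytic$valid[ends]
  starts <- starts[ok]; ends <- ends[ok]
  cyc <- rep.int(seq_along(starts), ends - starts + 1L)
  idx <- sequence(ends - starts + 1L, from = starts)
  ca <- tabulate(cyc[sa[idx] == 1L], length(starts))
  cb <- tabulate(cyc[sb[idx] == 1L], length(starts))
  qual <- which(ca == 1L & cb == 1L)
  if (length(qual) == 0) stop("no cycles with exactly one spike from each unit")
  first_in <- function(s, k) which(s[starts[k]:ends[k]] == 1L)[1]
  ta <- vapply(qual, function(k) first_in(sa, k), numeric(1))
  tb <- vapply(qual, function(k) first_in(sb, k), numeric(1))
  ties <- ta == tb
  frac <- mean(ta[!ties] < tb[!ties])
  out <- list(fraction = frac, n_cycles = sum(!ties), n_ties = sum(ties))
  if (deciles) {
    amp <- clc_amplitude(analytic)
    camp <- vapply(qual[!ties], function(k)
      mean(amp[starts[k]:ends[k]]), numeric(1))
    dec <- cut(rank(camp, ties.method = "first"),
               breaks = seq(0, length(camp), length.out = 11),
               labels = FALSE)
    firstA <- (ta < tb)[!ties]
    out$per_decile <- data.frame(
      decile = 1:10,
      fraction = as.numeric(tapply(firstA, dec, mean)),
      n = as.numeric(tabulate(dec, 10)))
  }
  class(out) <- "first_spiker"
  out
}

#' @export
print.first_spiker <- function(x, ...) {
  cat("First-spiker fraction: ", signif(100 * x$fraction, 3), "% of ",
      x$n_cycles, " qualifying cycles (", x$n_ties,
      " same-bin ties excluded)\n", sep = "")
  if (!is.null(x$per_decile)) {
    cat("  by amplitude decile:\n")
    print(x$per_decile, row.names = FALSE)
  }
  invisible(x)
}
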