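# Macro-scale phase relations: inter-hemispheric phase differences, their
# von Mises description, the distance law of pairwise phase concentration
# across an array, and lagged conditioning of amplitudes on the phase
# difference.

#' Inter-hemispheric phase-difference series
#'
#' Wrapped difference `theta_L - theta_R` per sample; the validity mask is
#' the conjunction of the input masks.
#'
#' @param left,right `analytic_signal`s of equal length and center
#'   frequency.
#' @return object of class `phase_diff`: numeric `phi` in `[-pi, pi)`,
#'   logical `valid`, `fs`, `v0`.
#' @export
phase_difference <- function(left, right) {
  stopifnot(inherits(left, "analytic_signal"), inherits(right, "analytic_signal"))
  if (length(left$z) != length(right$z))
    stop("signal lengths differ (", length(left$z), " vs ", length(right$z), ")")
  if (left$v0 != right$v0)
    stop("center frequencies differ (", left$v0, " vs ", right$v0, " Hz)")
  structure(list(phi = wrap_angle(clc_phase(left) - clc_phase(right)),
                 valid = left$valid & right$valid,
                 fs = left$fs, v0 = left$v0),
            class = "phase_diff")
}

#' @export
print.phase_diff <- function(x, ...) {
  cm <- circ_mean_R(x$phi[x$valid])
  cat("Phase-difference series at ", x$v0, " Hz: circular mean ",
      signif(cm$mu, 3), " rad, resultant length ", signif(cm$R, 3), "\n",
      sep = "")
  invisible(x)
}

#' Histogram and von Mises fit of a phase-difference distribution
#'
#' Normalized histogram over `[-pi, pi)` plus the maximum-likelihood von
#' Mises parameters: mean direction from the circular mean, concentration
#' from exact inversion of the mean resultant length (capped for
#' near-degenerate series).
#'
#' @param series a `phase_diff` or numeric angle vector.
#' @param n_bins histogram bins.
#' @param cap concentration ceiling for degenerate input.
#' @return object of class `phase_diff_density`: `breaks`, `density`
#'   (sums to 1 over bins), `mu`, `kappa`.
#' @export
fit_phase_diff_distribution <- function(series, n_bins = 36, cap = 50) {
  phi <- if (inherits(series, "phase_diff")) series$phi[series$valid]
         else as.numeric(series)
  if (length(phi) < 1000)
    stop("need at least 1000 valid samples, got ", length(phi))
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  h <- tabulate(findInterval(wrap_angle(phi), breaks,
                             rightmost.closed = TRUE), n_bins)
  cm <- circ_mean_R(phi)
  if (cm$R >= vm_A(cap))
    warning("near-degenerate phase-difference series; kappa capped at ", cap)
  structure(list(breaks = breaks, density = h / sum(h),
                 mu = cm$mu, kappa = vm_A_inv(cm$R, cap), R = cm$R,
                 n = length(phi)),
            class = "phase_diff_density")
}

#' @export
print.phase_diff_density <- function(x, ...) {
  cat("Phase-difference distribution: von Mises mean ", signif(x$mu, 3),
      " rad, kappa = ", signif(x$kappa, 4), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.phase_diff_density <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  wd <- diff(x$breaks[1:2])
  graphics::plot(mids, x$density / wd, type = "s", xlab = "phase difference (rad)",
                 ylab = "density", ...)
  vm <- exp(x$kappa * cos(mids - x$mu)) /
    (2 * pi * besselI(x$kappa, 0, expon.scaled = TRUE) * exp(x$kappa))
  graphics::lines(mids, vm, col = "red")
  invisible(x)
}

# Pairwise von Mises concentration of filtered phase differences for all
# channel pairs of an array.
pairwise_kappa <- function(array, v0 = NULL, s0 = NULL, cap = 50) {
  stopifnot(inherits(array, "lfp_array"))
  if (is.null(v0)) v0 <- array$f0
  nch <- ncol(array$lfp)
  U <- NULL
  for (c_ in seq_len(nch)) {
    a <- filter_signal(array$lfp[, c_], v0, s0, array$fs)
    if (is.null(U)) {
      U <- matrix(0i, sum(a$valid), nch)
      keep <- a$valid
    }
    U[, c_] <- a$z[keep] / Mod(a$z[keep])
  }
  G <- Mod(t(Conj(U)) %*% U) / nrow(U)   # mean resultant length per pair
  K <- matrix(vm_A_inv(pmin(G[upper.tri(G)], 1), cap), nrow = 1)
  out <- matrix(NA_real_, nch, nch)
  out[upper.tri(out)] <- K
  out
}

#' Distance law of pairwise phase concentration on an array
#'
#' Filters all channels at `v0`, estimates the von Mises concentration of
#' the phase difference for every channel pair, pools pairs within distance
#' classes (grid distances rounded to 1e-6 mm), and fits the least-squares
#' line of mean concentration on distance.
#'
#' @param array an `lfp_array`.
#' @param v0 center frequency (defaults to the array's beta peak).
#' @param s0 optional duration parameter.
#' @param cap concentration ceiling; if more than half of all pairs sit at
#'   the cap the fit is flagged degenerate.
#' @return object of class `distance_kappa_fit`: per-class table
#'   (`distance`, `kappa`, `n_pairs`), `intercept`, `slope` (per mm),
#'   `degenerate` flag.
#' @export
distance_kappa_fit <- function(array, v0 = NULL, s0 = NULL, cap = 50) {
  K <- pairwise_kappa(array, v0, s0, cap)
  D <- as.matrix(stats::dist(array$coords))
  d <- round(D[upper.tri(D)], 6)
  k <- K[upper.tri(K)]
  if (length(unique(d)) < 2) stop("need at least two distinct distances")
  tab <- do.call(rbind, lapply(split(k, d), function(v)
    data.frame(kappa = mean(v), n_pairs = length(v))))
  tab <- data.frame(distance = as.numeric(rownames(tab)), tab,
                    row.names = NULL)
  degenerate <- mean(k >= cap - 1e-9) > 0.5
  fit <- stats::lm(kappa ~ distance, data = tab)
  structure(list(table = tab, intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 degenerate = degenerate, cap = cap),
            class = "distance_kappa_fit")
}

#' @export
print.distance_kappa_fit <- function(x, ...) {
  cat("Pairwise phase concentration vs distance: kappa = ",
      signif(x$intercept, 4), " ", ifelse(x$slope < 0, "-", "+"), " ",
      signif(abs(x$slope), 4), " * d[mm]",
      if (x$degenerate) "  (DEGENERATE: most pairs at cap)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.distance_kappa_fit <- function(x, ...) {
  graphics::plot(x$table$distance, x$table$kappa, pch = 16,
                 xlab = "inter-electrode distance (mm)",
                 ylab = expression(hat(kappa)), ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Lagged conditioning of beta amplitudes on the phase difference
#'
#' For each lag, bins the (lagged) amplitudes by the phase difference with
#' equal-count bins and reports (i) the conditioned mean amplitude per
#' hemisphere and (ii) the inter-hemispheric amplitude correlation within
#' each bin.  Positive lag means the amplitude series is shifted later
#' than the phase-difference series (the phase difference predicts
#' amplitudes `lag` ms in the future).
#'
#' @param phase_diff a `phase_diff` object.
#' @param amp_L,amp_R amplitude series (numeric, aligned with the phase
#'   difference).
#' @param lags_ms integer lags in ms.
#' @param n_bins equal-count phase-difference bins.
#' @return object of class `lagged_conditioning`: per-lag list of curves,
#'   data.frame `ranges` (`lag`, `range_mean`, `range_corr`), and the
#'   range-maximizing lags `best_lag_mean`, `best_lag_corr`.
#' @export
lagged_amplitude_conditioning <- function(phase_diff, amp_L, amp_R,
                                          lags_ms = seq(-60, 60, by = 2),
                                          n_bins = 16) {
  stopifnot(inherits(phase_diff, "phase_diff"))
  if (length(lags_ms) == 0) stop("empty lag list")
  n <- length(phase_diff$phi)
  stopifnot(length(amp_L) == n, length(amp_R) == n)
  ms_per_sample <- 1000 / phase_diff$fs
  curves <- list()
  ranges <- data.frame(lag = lags_ms, range_mean = NA_real_,
                       range_corr = NA_real_)
  for (i in seq_along(lags_ms)) {
    lag <- as.integer(round(lags_ms[i] / ms_per_sample))
    if (abs(lag) >= n) stop("lag exceeds series length")
    # positive lag: amplitude `lag` ms later than the phase difference, so
    # advance the amplitude series before pairing sample-wise
    aL <- shift_series(amp_L, -lag)
    aR <- shift_series(amp_R, -lag)
    ok <- phase_diff$valid & shift_series(phase_diff$valid, -lag)
    ec <- equal_count_condition(phase_diff$phi[ok], aL[ok], n_bins)
    mR <- equal_count_condition(phase_diff$phi[ok], aR[ok], n_bins)
    aLs <- aL[ok][seq_len(ec$N_t)]; aRs <- aR[ok][seq_len(ec$N_t)]
    corr <- vapply(ec$groups, function(g)
      stats::cor(aLs[g], aRs[g]), numeric(1))
    curves[[i]] <- list(lag = lags_ms[i], support = ec$support,
                        mean_L = ec$mean, mean_R = mR$mean, corr = corr,
                        P = ec$P)
    ranges$range_mean[i] <- max(diff(range(ec$mean)), diff(range(mR$mean)))
    ranges$range_corr[i] <- diff(range(corr))
  }
  structure(list(curves = curves, ranges = ranges,
                 best_lag_mean = ranges$lag[which.max(ranges$range_mean)],
                 best_lag_corr = ranges$lag[which.max(ranges$range_corr)]),
            class = "lagged_conditioning")
}

#' @export
print.lagged_conditioning <- function(x, ...) {
  cat("Lagged phase-difference conditioning over ", nrow(x$ranges),
      " lags\n  mean-amplitude range maximal at lag ", x$best_lag_mean,
      " ms; correlation range maximal at lag ", x$best_lag_corr, " ms\n",
      sep = "")
  invisible(x)
}
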