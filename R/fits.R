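# Parametric fits of the binned rate mappings.
#
# Four model families, fitted by least squares to the equal-count binned
# rates (trust-region Levenberg-Marquardt with a multi-start grid where the
# problem is nonlinear):
#   F_S(a)      = p1 + p2 * tanh((a - p3)/(2 p4))          (amplitude)
#   F_C(theta)  = p1 + p2 * cos(theta - p3), p2 >= 0       (phase)
#   F_D(phi)    = p1 + p2 * exp(p3 * cos(phi - p4)), p3 > 0 (phase diff)
#   F_B(a,th)   = p1 + p2 tanh((a - p3)/(2 p4))
#                    + (p5 a + p6 a^2) cos(th - p7)        (joint)
# In the joint model the phase component R_PHASE is the unit-amplitude
# cosine cos(th - p7), so the quadratic weight is exactly
# w_AMP(a) = p5 a + p6 a^2 (b1 = p5, b2 = p6) and the decomposition
# R_BETA = R_AMP + w_AMP * R_PHASE holds identically.

#' Sigmoid, cosine, von Mises and joint model curves
#'
#' Closed-form evaluation of the fitted families at given parameters.
#'
#' @param a amplitude; `theta` phase (rad); `phi` phase difference (rad).
#' @param p numeric parameter vector (length 4, 3, 4 or 7 by family).
#' @return numeric rates in spikes/s.
#' @export
F_S <- function(a, p) p[[1]] + p[[2]] * tanh((a - p[[3]]) / (2 * p[[4]]))

#' @rdname F_S
#' @export
F_C <- function(theta, p) p[[1]] + p[[2]] * cos(theta - p[[3]])

#' @rdname F_S
#' @export
F_D <- function(phi, p) p[[1]] + p[[2]] * exp(p[[3]] * cos(phi - p[[4]]))

#' @rdname F_S
#' @param theta phase for the joint model.
#' @export
F_B <- function(a, theta, p)
  p[[1]] + p[[2]] * tanh((a - p[[3]]) / (2 * p[[4]])) +
  (p[[5]] * a + p[[6]] * a^2) * cos(theta - p[[7]])

# Multi-start bounded Levenberg-Marquardt least squares; returns the best
# converged start or fails loudly.
nls_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best))
    stop("nonlinear least squares did not converge from any start")
  best
}

new_clc_fit <- function(subclass, pars, mapping, fitted, family, label) {
  rss <- sum((mapping$R - fitted)^2)
  tss <- sum((mapping$R - mean(mapping$R))^2)
  structure(list(coefficients = pars, mapping = mapping, fitted = fitted,
                 residuals = mapping$R - fitted, rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 family = family, label = label),
            class = c(subclass, "clc_fit"))
}

#' Fit the 4-parameter sigmoid amplitude-to-rate mapping
#'
#' Least squares of `F_S` to the binned rates; the width `p4` is bounded
#' positive so the sign of the half-range `p2` carries the direction of the
#' mapping (increase vs decrease of rate with beta amplitude).
#'
#' @param mapping a `binned_mapping` over amplitude (>= 4 bins).
#' @return object of classes `sigmoid_fit`, `clc_fit` with coefficients
#'   `p1` (offset, spikes/s), `p2` (signed half-range), `p3` (inflection
#'   amplitude), `p4` (width), plus fitted values and goodness of fit.
#' @export
fit_sigmoid <- function(mapping) {
  stopifnot(inherits(mapping, "binned_mapping"), mapping$n_bins >= 4)
  A <- mapping$A; R <- mapping$R
  b <- sigmoid_bounds(A, R)
  half <- (max(R) - min(R)) / 2
  starts <- list()
  for (sgn in c(1, -1)) for (q in stats::quantile(A, c(0.25, 0.75)))
    for (w in c(0.1, 0.3))
      starts[[length(starts) + 1L]] <-
        c(p1 = mean(R), p2 = sgn * max(half, 1e-3), p3 = unname(q), p4 = w)
  fit <- nls_multistart(function(p) F_S(A, p) - R, starts,
                        lower = b$lower, upper = b$upper)
  new_clc_fit("sigmoid_fit", fit$par, mapping, F_S(A, fit$par),
              "sigmoid", "amplitude-to-rate")
}

# Identifiability bounds for the sigmoid on the observed support: an
# inflection far outside the support, a width much larger than the support,
# or a half-range far beyond the observed rate range all parameterize
# curves indistinguishable from a line over the data and let p2/p4 run off
# along a flat ridge of the objective.
sigmoid_bounds <- function(A, R) {
  wA <- max(diff(range(A)), 1e-6)
  rr <- max(max(R) - min(R), 1)
  list(lower = c(-Inf, -3 * rr, min(A) - wA, 1e-3),
       upper = c(Inf, 3 * rr, max(A) + wA, 2 * wA))
}

#' Fit the cosine phase-to-rate mapping
#'
#' `F_C` is linear in `(p1, p2 cos p3, p2 sin p3)`, so the fit is exact
#' linear least squares; the modulation depth `p2` (maximum minus baseline
#' rate) is nonnegative by construction and `p3` is the preferred phase.
#'
#' @param mapping a `binned_mapping` over phase covering the circle.
#' @return object of classes `cosine_fit`, `clc_fit` with coefficients
#'   `p1` (baseline), `p2` (depth, >= 0), `p3` (preferred phase, rad).
#' @export
fit_cosine <- function(mapping) {
  stopifnot(inherits(mapping, "binned_mapping"))
  th <- mapping$A; R <- mapping$R
  if (diff(range(th)) < pi)
    stop("phase support does not cover the circle")
  X <- cbind(1, cos(th), sin(th))
  b <- stats::lm.fit(X, R)$coefficients
  p2 <- sqrt(b[2]^2 + b[3]^2)
  p3 <- atan2(b[3], b[2])
  pars <- c(p1 = unname(b[1]), p2 = unname(p2), p3 = wrap_angle(unname(p3)))
  new_clc_fit("cosine_fit", pars, mapping, F_C(th, pars),
              "cosine", "phase-to-rate")
}

#' Fit the von Mises-type phase-difference-to-rate mapping
#'
#' Least squares of `F_D` with the concentration `p3` bounded positive.
#' The fitted peak-to-trough modulation
#' `|p2| * (exp(p3) - exp(-p3))` is reported as `modulation`; values near
#' zero indicate no dependence on the phase difference.
#'
#' @param mapping a `binned_mapping` over the inter-hemispheric phase
#'   difference.
#' @return object of classes `vonmises_rate_fit`, `clc_fit` with
#'   coefficients `p1` (offset), `p2` (scale), `p3` (concentration > 0),
#'   `p4` (preferred phase difference, rad).
#' @export
fit_vonmises_rate <- function(mapping) {
  stopifnot(inherits(mapping, "binned_mapping"))
  ph <- mapping$A; R <- mapping$R
  if (diff(range(ph)) < pi)
    stop("phase-difference support does not cover the circle")
  cf <- fit_cosine(mapping)
  p4c <- unname(stats::coef(cf)[3])
  starts <- list()
  for (p4 in c(p4c, wrap_angle(p4c + pi))) for (k in c(0.5, 1.5, 3)) {
    sc <- (max(R) - min(R)) / max(exp(k) - exp(-k), 1e-6)
    for (sgn in c(1, -1))
      starts[[length(starts) + 1L]] <-
        c(p1 = mean(R), p2 = sgn * max(sc, 1e-4), p3 = k, p4 = p4)
  }
  fit <- nls_multistart(function(p) F_D(ph, p) - R, starts,
                        lower = c(-Inf, -Inf, 1e-3, -2 * pi),
                        upper = c(Inf, Inf, 50, 2 * pi))
  pars <- fit$par
  pars[4] <- wrap_angle(pars[4])
  names(pars) <- c("p1", "p2", "p3", "p4")
  out <- new_clc_fit("vonmises_rate_fit", pars, mapping, F_D(ph, pars),
                     "vonmises", "phase-difference-to-rate")
  out$modulation <- abs(pars[[2]]) * (exp(pars[[3]]) - exp(-pars[[3]]))
  out
}

#' Fit the 7-parameter joint beta-to-rate mapping
#'
#' Least squares of `F_B` over all cells of a joint amplitude x phase rate
#' matrix.  Starts are seeded from the univariate sigmoid fit of the
#' amplitude marginal and the cosine fit of the phase marginal.  The
#' returned object exposes the component callables `R_AMP(a)`,
#' `R_PHASE(theta)` (unit cosine) and `w_AMP(a) = b1 a + b2 a^2` with
#' `b1 = p5`, `b2 = p6`, so `F_B = R_AMP + w_AMP * R_PHASE` exactly.
#'
#' @param joint a `joint_binning` object.
#' @return object of classes `beta_rate_fit`, `clc_fit`; coefficients
#'   `p1..p7`, weight coefficients `b1`, `b2`, and component functions.
#' @export
fit_beta_rate <- function(joint) {
  stopifnot(inherits(joint, "joint_binning"))
  if (joint$n_ab < 2) stop("rank-deficient design: need >= 2 amplitude bins")
  a <- joint$amp_support[row(joint$rates)]
  th <- joint$phase_support
  R <- joint$rates
  # marginal seeds
  amp_marg <- structure(list(variable = "amplitude", A = joint$amp_support,
                             R = rowMeans(R), n_bins = joint$n_ab,
                             P = joint$P * joint$n_pb, N = joint$N,
                             N_t = joint$N_t, fs = joint$fs),
                        class = "binned_mapping")
  sf <- stats::coef(fit_sigmoid(amp_marg))
  ph_marg <- structure(list(variable = "phase", A = colMeans(th),
                            R = colMeans(R), n_bins = joint$n_pb,
                            P = joint$P * joint$n_ab, N = joint$N,
                            N_t = joint$N_t, fs = joint$fs),
                       class = "binned_mapping")
  cf <- stats::coef(fit_cosine(ph_marg))
  av <- as.vector(a); thv <- as.vector(th); Rv <- as.vector(R)
  b <- sigmoid_bounds(joint$amp_support, Rv)
  starts <- list()
  for (p7 in c(cf[[3]], wrap_angle(cf[[3]] + pi)))
    for (p5 in c(cf[[2]], 0.25 * cf[[2]], -cf[[2]]))
      starts[[length(starts) + 1L]] <-
        c(p1 = sf[[1]], p2 = sf[[2]], p3 = min(max(sf[[3]], b$lower[3]), b$upper[3]),
          p4 = min(sf[[4]], b$upper[4]),
          p5 = p5, p6 = 0, p7 = p7)
  fit <- nls_multistart(function(p) F_B(av, thv, p) - Rv, starts,
                        lower = c(b$lower, -Inf, -Inf, -2 * pi),
                        upper = c(b$upper, Inf, Inf, 2 * pi))
  pars <- fit$par
  # canonical branch of the exact symmetry (p5, p6, p7) ~ (-p5, -p6, p7 + pi):
  # the weight at the mean amplitude (a = 1 after normalization) is >= 0,
  # matching the p2 >= 0 convention of the univariate cosine fit.
  if (pars[5] + pars[6] < 0) {
    pars[5:6] <- -pars[5:6]
    pars[7] <- pars[7] + pi
  }
  pars[7] <- wrap_angle(pars[7])
  names(pars) <- paste0("p", 1:7)
  fitted <- F_B(av, thv, pars)
  rss <- sum((Rv - fitted)^2)
  tss <- sum((Rv - mean(Rv))^2)
  structure(list(coefficients = pars, joint = joint,
                 fitted = matrix(fitted, joint$n_ab, joint$n_pb),
                 residuals = R - matrix(fitted, joint$n_ab, joint$n_pb),
                 rss = rss, r_squared = 1 - rss / tss,
                 b1 = pars[[5]], b2 = pars[[6]],
                 R_AMP = function(a) F_S(a, pars[1:4]),
                 R_PHASE = function(theta) cos(theta - pars[[7]]),
                 w_AMP = function(a) pars[[5]] * a + pars[[6]] * a^2,
                 family = "beta_rate", label = "joint beta-to-rate"),
            class = c("beta_rate_fit", "clc_fit"))
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.clc_fit <- function(object, ...) object$coefficients

#' @export
residuals.clc_fit <- function(object, ...) object$residuals

#' @export
print.clc_fit <- function(x, ...) {
  cat("CLC ", x$label, " fit (", x$family, ")\n", sep = "")
  print(signif(x$coefficients, 5))
  cat("R-squared on binned rates:", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' @export
summary.clc_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              r_squared = object$r_squared, rss = object$rss,
              family = object$family, label = object$label,
              n_bins = if (!is.null(object$mapping)) object$mapping$n_bins
                       else length(object$fitted))
  class(out) <- "summary.clc_fit"
  out
}

#' @export
print.summary.clc_fit <- function(x, ...) {
  cat("CLC", x$label, "fit\n  family:", x$family, "\n  bins:", x$n_bins,
      "\n  RSS:", signif(x$rss, 5), " R2:", signif(x$r_squared, 4), "\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Predicted rates from fitted CLC mappings
#'
#' @param object a fitted mapping.
#' @param newdata numeric vector of conditioning values (amplitude, phase,
#'   or phase difference); for `beta_rate_fit`, a list or data.frame with
#'   elements `a` and `theta`.  Defaults to the fit's own bin supports.
#' @param ... unused.
#' @return predicted rates in spikes/s.
#' @export
predict.clc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  p <- object$coefficients
  switch(object$family,
         sigmoid = F_S(newdata, p),
         cosine = F_C(newdata, p),
         vonmises = F_D(newdata, p),
         stop("unknown family"))
}

#' @export
predict.beta_rate_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  F_B(newdata$a, newdata$theta, object$coefficients)
}

#' @export
plot.clc_fit <- function(x, ...) {
  m <- x$mapping
  graphics::plot(m$A, m$R, pch = 16, xlab = m$variable,
                 ylab = "spike rate (spikes/s)",
                 main = paste("CLC", x$label), ...)
  xx <- seq(min(m$A), max(m$A), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = "red", lwd = 2)
  invisible(x)
}

#' Simulate spike trains from a fitted univariate mapping
#'
#' Bernoulli draws at 1-ms resolution with the fitted rate evaluated on a
#' conditioning series.
#'
#' @param object fitted mapping.
#' @param nsim number of trains.
#' @param seed optional RNG seed.
#' @param newdata conditioning series at which to evaluate the rate.
#' @param ... unused.
#' @return list of [spike_train()] objects.
#' @export
simulate.clc_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- pmax(predict(object, newdata), 0)
  if (any(r > 1000)) stop("fitted rate exceeds 1000 spikes/s")
  lapply(seq_len(nsim), function(i)
    spike_train(stats::rbinom(length(r), 1L, r / 1000),
                unit_id = sprintf("sim%02d", i), fs = object$mapping$fs))
}

#' Fit a CLC rate mapping (umbrella interface)
#'
#' Bins spikes on the requested conditioning variable with equal-count bins
#' and fits the corresponding parametric family: sigmoid for amplitude,
#' cosine for phase, von Mises-type for the inter-hemispheric phase
#' difference, or the joint 7-parameter beta model.
#'
#' @param analytic a normalized `analytic_signal` (or, for
#'   `what = "phase_difference"`, the numeric phase-difference series with
#'   `valid`/`fs` supplied).
#' @param spikes a [spike_train()] or binary vector.
#' @param what conditioning variable.
#' @param n_bins bins for univariate mappings.
#' @param n_ab,n_pb bins for the joint mapping.
#' @param ... passed to the binning routine.
#' @return a fitted `clc_fit` object of the family-specific subclass.
#' @export
clc_fit <- function(analytic, spikes,
                    what = c("amplitude", "phase", "phase_difference", "beta"),
                    n_bins = 25, n_ab = 8, n_pb = 16, ...) {
  what <- match.arg(what)
  if (what == "beta")
    return(fit_beta_rate(joint_binning(analytic, spikes = spikes,
                                       n_ab = n_ab, n_pb = n_pb, ...)))
  x <- switch(what,
              amplitude = clc_amplitude(analytic),
              phase = clc_phase(analytic),
              phase_difference = if (inherits(analytic, "analytic_signal"))
                stop("phase_difference requires a numeric series, see phase_difference()")
                else analytic)
  valid <- if (inherits(analytic, "analytic_signal")) analytic$valid else NULL
  fs <- if (inherits(analytic, "analytic_signal")) analytic$fs else NULL
  m <- equal_count_binning(x, spikes, n_bins = n_bins, fs = fs,
                           valid = valid, ...)
  m$variable <- what
  switch(what,
         amplitude = fit_sigmoid(m),
         phase = fit_cosine(m),
         phase_difference = fit_vonmises_rate(m))
}
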