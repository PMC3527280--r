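# Spike-train synthesis from the beta-to-rate model.
#
# The instantaneous rate of a unit composes additively, then clips at zero:
#   rate(t) = r_baseline + r_trial(t) + r_target(t)
#           + R_AMP(a_t) + w_AMP(a_t) * R_PHASE(theta_t) [+ phase-diff term]
# with R_AMP(a) = p2 tanh((a - p3)/(2 p4)) (zero-mean-ish deviation; the
# offset lives in r_baseline), R_PHASE(theta) = cos(theta - pref) with unit
# amplitude, w_AMP(a) = b1 a + b2 a^2, and an optional von Mises-type term
# pd_p2 exp(pd_p3 cos(phi - pd_p4)) in the inter-hemispheric phase
# difference phi.  Spikes are per-1-ms Bernoulli draws with probability
# rate * 1 ms.

#' Construct per-task ground-truth parameters for one synthetic unit
#'
#' @param r_baseline tonic rate in spikes/s.
#' @param amp sigmoid amplitude-to-rate deviation `c(p2, p3, p4)`
#'   (half-range, inflection amplitude, width).
#' @param phase phase coupling `c(b1, b2, pref)`: quadratic weight
#'   coefficients of `w_AMP` and the preferred phase (rad).
#' @param pd optional phase-difference coupling `c(p2, p3, p4)` of the von
#'   Mises-type term.
#' @param target optional direction tuning `c(depth, pref)` with `pref` in
#'   1..8; adds `depth * cos(2 pi (target - pref)/8)` within trials.
#' @param trial optional trial-stage offsets `c(move, reward)` in spikes/s.
#' @param target_mult optional multiplicative target gain on the phase
#'   modulation depth (interaction switch).
#' @return a list of class `unit_params`.
#' @export
unit_params <- function(r_baseline = 20, amp = c(p2 = 0, p3 = 1, p4 = 0.2),
                        phase = c(b1 = 0, b2 = 0, pref = 0), pd = NULL,
                        target = NULL, trial = NULL, target_mult = NULL) {
  stopifnot(r_baseline >= 0, amp[[3]] > 0)
  p <- list(r_baseline = r_baseline, amp = amp, phase = phase, pd = pd,
            target = target, trial = trial, target_mult = target_mult)
  class(p) <- "unit_params"
  p
}

#' Ground truth for one unit over both tasks
#'
#' @param unit_id unit label.
#' @param MC,BC `unit_params` for each task.
#' @return list of class `unit_ground_truth`.
#' @export
unit_ground_truth <- function(unit_id, MC, BC) {
  stopifnot(inherits(MC, "unit_params"), inherits(BC, "unit_params"))
  structure(list(unit_id = unit_id, MC = MC, BC = BC),
            class = "unit_ground_truth")
}

# Per-sample trial annotations: in-trial flag, current target, and stage
# (1 move-to-center, 2 move-to-target, 3 reward-on, 0 elsewhere).
trial_annotation <- function(trials, n) {
  target <- integer(n)
  stage <- integer(n)
  if (!is.null(trials)) {
    for (i in seq_len(nrow(trials))) {
      a <- max(1L, trials$t_center_on[i] + 1L)
      b <- min(n, trials$t_reward_off[i])
      if (a > n) break
      target[a:b] <- trials$target_id[i]
      s1 <- min(n, trials$t_center_enter[i]); stage[a:s1] <- 1L
      s2a <- min(n, trials$t_go[i] + 1L); s2b <- min(n, trials$t_target_enter[i])
      if (s2a <= s2b) stage[s2a:s2b] <- 2L
      s3a <- min(n, trials$t_reward_on[i] + 1L)
      if (s3a <= b) stage[s3a:b] <- 3L
    }
  }
  list(target = target, stage = stage)
}

#' Ground-truth instantaneous rate of a synthetic unit
#'
#' Composes the additive rate model on a given analytic signal; the oracle
#' counterpart of [generate_spikes()].
#'
#' @param gt a `unit_ground_truth`.
#' @param task `"MC"` or `"BC"`.
#' @param analytic normalized `analytic_signal` (mean amplitude 1).
#' @param phase_diff optional inter-hemispheric phase-difference series.
#' @param trials optional `trial_table`.
#' @return numeric rate series in spikes/s (clipped at 0; modulation terms
#'   are zeroed on invalid edge samples).
#' @export
true_rate_series <- function(gt, task, analytic, phase_diff = NULL,
                             trials = NULL) {
  stopifnot(inherits(gt, "unit_ground_truth"), task %in% c("MC", "BC"),
            inherits(analytic, "analytic_signal"))
  p <- gt[[task]]
  a <- clc_amplitude(analytic)
  th <- clc_phase(analytic)
  n <- length(a)
  ann <- trial_annotation(trials, n)

  r <- rep(p$r_baseline, n)
  if (!is.null(p$trial)) {
    r[ann$stage == 2L] <- r[ann$stage == 2L] + p$trial[[1]]
    r[ann$stage == 3L] <- r[ann$stage == 3L] + p$trial[[2]]
  }
  tgt_cos <- numeric(n)
  intr <- ann$target > 0L
  if (any(intr)) tgt_cos[intr] <- cos(2 * pi * (ann$target[intr] -
                                                  (p$target[[2]] %||% 1)) / 8)
  if (!is.null(p$target)) r <- r + ifelse(intr, p$target[[1]] * tgt_cos, 0)

  amp_term <- p$amp[[1]] * tanh((a - p$amp[[2]]) / (2 * p$amp[[3]]))
  w_amp <- p$phase[[1]] * a + p$phase[[2]] * a^2
  if (!is.null(p$target_mult))
    w_amp <- w_amp * ifelse(intr, 1 + p$target_mult * tgt_cos, 1)
  mod <- amp_term + w_amp * cos(th - p$phase[[3]])
  if (!is.null(p$pd) && !is.null(phase_diff))
    mod <- mod + p$pd[[1]] * exp(p$pd[[2]] * cos(phase_diff - p$pd[[3]]))
  mod[!analytic$valid] <- 0
  pmax(r + mod, 0)
}

#' Generate a spike train from the beta-to-rate ground truth
#'
#' Per-1-ms-bin Bernoulli draws with probability `rate(t) * 1 ms`.
#'
#' @inheritParams true_rate_series
#' @param seed integer RNG seed.
#' @param unit_id label for the returned train.
#' @return a [spike_train()].
#' @export
generate_spikes <- function(gt, task, analytic, phase_diff = NULL,
                            trials = NULL, seed = NULL, unit_id = gt$unit_id) {
  rate <- true_rate_series(gt, task, analytic, phase_diff, trials)
  if (any(rate > 1000))
    stop("ground-truth rate exceeds 1000 spikes/s (1-ms bin saturation)")
  if (!is.null(seed)) set.seed(seed)
  spike_train(stats::rbinom(length(rate), 1L, rate / 1000), unit_id = unit_id,
              fs = analytic$fs)
}

#' Synthesize a random ensemble of ground-truth units
#'
#' Draws per-unit parameters spanning the qualitative diversity of
#' amplitude slopes (positive, negative, flat), phase preferences, weight
#' curvature and direction tuning.  With `remap = TRUE` the BC parameters
#' differ from MC: preferred phases shift earlier by `phase_shift` rad
#' across the ensemble (plus per-unit jitter, so the remap is not a pure
#' rotation), and amplitude slopes and phase weights are independently
#' redrawn (sign flips included); with `remap = FALSE` both tasks share
#' identical parameters.
#'
#' @param n_units ensemble size.
#' @param seed integer RNG seed.
#' @param remap whether BC parameters are remapped relative to MC.
#' @param phase_shift ensemble-wide BC-earlier preferred-phase shift (rad).
#' @param phase_jitter per-unit SD (rad) of the idiosyncratic component of
#'   the preferred-phase remap.
#' @return list of `unit_ground_truth` objects.
#' @export
synthesize_units <- function(n_units, seed = NULL, remap = TRUE,
                             phase_shift = 0.8, phase_jitter = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_units), function(i) {
    base <- stats::runif(1, 8, 30)
    draw_amp <- function() c(p2 = sample(c(-1, 1), 1) * stats::runif(1, 2, 8),
                             p3 = stats::runif(1, 0.8, 1.2),
                             p4 = stats::runif(1, 0.15, 0.4))
    pref_mc <- stats::runif(1, -pi, pi)
    mk <- function(amp, pref) unit_params(
      r_baseline = base, amp = amp,
      phase = c(b1 = stats::runif(1, 1, 4), b2 = stats::runif(1, -0.5, 1),
                pref = pref),
      target = c(depth = stats::runif(1, 0, 6), pref = sample(1:8, 1)),
      trial = c(move = stats::runif(1, -6, 2), reward = stats::runif(1, -2, 4)))
    mc <- mk(draw_amp(), pref_mc)
    bc <- if (remap)
      mk(draw_amp(), wrap_angle(pref_mc - phase_shift +
                                  stats::rnorm(1, 0, phase_jitter)))
    else mc
    unit_ground_truth(sprintf("unit%03d", i), MC = mc, BC = bc)
  })
}

#' Write and read ground-truth records
#'
#' JSON round trip of the full parameter set (both tasks per unit),
#' sufficient for parameter-recovery scoring.
#'
#' @param gts list of `unit_ground_truth` objects.
#' @param path output file path; its directory must exist.
#' @return `export_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` the reconstructed list.
#' @export
export_ground_truth <- function(gts, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (inherits(gts, "unit_ground_truth")) gts <- list(gts)
  as_obj <- function(p) lapply(unclass(p), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  plain <- lapply(gts, function(u) {
    u <- unclass(u)
    u$MC <- as_obj(u$MC)
    u$BC <- as_obj(u$BC)
    u
  })
  jsonlite::write_json(plain, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(u) {
    fix <- function(p) {
      p <- lapply(p, function(x) {
        if (is.list(x)) x <- unlist(x)
        if (length(x) == 0) NULL else x
      })
      do.call(unit_params, p[!vapply(p, is.null, logical(1))])
    }
    unit_ground_truth(u$unit_id, MC = fix(u$MC), BC = fix(u$BC))
  })
}
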