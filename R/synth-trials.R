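# Synthetic behavioral trial tables for the delayed center-out task.
#
# Trials follow the task's event grammar: center cue on -> cursor enters
# center -> hold (500 ms Manual Control / 100 ms Brain Control) -> go cue ->
# movement -> cursor enters target -> target hold (400 ms MC / 50 ms BC) ->
# reward on (500 ms) -> reward off.  Movement durations are drawn from a
# configurable law and capped at the 10-s trial-error limit.

task_params <- function(task) {
  switch(task,
         MC = list(center_hold = 500, target_hold = 400, reward = 500),
         BC = list(center_hold = 100, target_hold = 50, reward = 500),
         stop("invalid task label '", task, "' (must be \"MC\" or \"BC\")"))
}

draw_durations <- function(law, n) {
  law <- as.list(law)
  d <- switch(law$dist %||% "lognormal",
              fixed = rep(law$value, n),
              uniform = stats::runif(n, law$min, law$max),
              lognormal = stats::rlnorm(n, law$meanlog %||% log(900),
                                        law$sdlog %||% 0.35),
              stop("unknown movement_duration_law distribution '", law$dist, "'"))
  if (any(d <= 0) || any(d > 10000))
    stop("movement_duration_law yields durations outside (0, 10000] ms")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic trial table
#'
#' @param task `"MC"` (Manual Control) or `"BC"` (Brain Control).
#' @param n_trials number of trials (>= 1).
#' @param movement_duration_law list describing the go-cue-to-target-entry
#'   duration distribution: `list(dist = "fixed", value = )`,
#'   `list(dist = "uniform", min = , max = )`, or
#'   `list(dist = "lognormal", meanlog = , sdlog = )` (default: lognormal with
#'   median 900 ms). Durations must lie in (0, 10000] ms.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param t_start time of the first center-cue onset in ms.
#' @return a `data.frame` of class `trial_table` with columns `trial_id`,
#'   `task`, `target_id` (1-8, balanced within +/-1 across the table),
#'   event timestamps in ms (`t_center_on`, `t_center_enter`, `t_go`,
#'   `t_target_enter`, `t_reward_on`, `t_reward_off`) and
#'   `movement_duration`.
#' @examples
#' tr <- generate_trials("MC", 8, list(dist = "fixed", value = 900), seed = 1)
#' all(tr$t_go - tr$t_center_enter == 500)
#' @export
generate_trials <- function(task, n_trials,
                            movement_duration_law = list(dist = "lognormal"),
                            seed = NULL, t_start = 1000) {
  p <- task_params(task)
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("n_trials must be a positive integer")
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)

  # balanced pseudo-random target assignment: shuffled blocks of 1..8
  blocks <- ceiling(n_trials / 8)
  targets <- unlist(lapply(seq_len(blocks), function(i) sample(1:8)))[seq_len(n_trials)]

  md <- round(draw_durations(movement_duration_law, n_trials))
  md <- pmax(md, 1)
  reach_center <- round(stats::runif(n_trials, 300, 800))
  iti <- round(stats::runif(n_trials, 500, 1500))

  t_center_on <- numeric(n_trials)
  t_center_on[1] <- t_start
  t_center_enter <- t_go <- t_target_enter <- t_reward_on <- t_reward_off <-
    numeric(n_trials)
  for (i in seq_len(n_trials)) {
    t_center_enter[i] <- t_center_on[i] + reach_center[i]
    t_go[i] <- t_center_enter[i] + p$center_hold
    t_target_enter[i] <- t_go[i] + md[i]
    t_reward_on[i] <- t_target_enter[i] + p$target_hold
    t_reward_off[i] <- t_reward_on[i] + p$reward
    if (i < n_trials) t_center_on[i + 1] <- t_reward_off[i] + iti[i]
  }
  out <- data.frame(trial_id = seq_len(n_trials), task = task,
                    target_id = targets,
                    t_center_on = t_center_on, t_center_enter = t_center_enter,
                    t_go = t_go, t_target_enter = t_target_enter,
                    t_reward_on = t_reward_on, t_reward_off = t_reward_off,
                    movement_duration = md)
  class(out) <- c("trial_table", "data.frame")
  validate_trial_table(out)
  out
}

# Enforce the trial-table invariants programmatically.
validate_trial_table <- function(tr) {
  p <- task_params(tr$task[1])
  ts <- as.matrix(tr[, c("t_center_on", "t_center_enter", "t_go",
                         "t_target_enter", "t_reward_on", "t_reward_off")])
  if (any(t(apply(ts, 1, diff)) <= 0))
    stop("trial timestamps must be strictly increasing within a trial")
  stopifnot(all(tr$t_go - tr$t_center_enter == p$center_hold),
            all(tr$t_reward_on - tr$t_target_enter == p$target_hold),
            all(tr$t_reward_off - tr$t_reward_on == p$reward),
            all(tr$movement_duration <= 10000),
            all(tr$movement_duration == tr$t_target_enter - tr$t_go),
            all(tr$target_id %in% 1:8))
  invisible(tr)
}

# Total time span covered by a trial table, in ms.
trial_span <- function(tr) max(tr$t_reward_off)

#' Spike train container
#'
#' A 1-kHz binary spike vector aligned with the LFP samples.
#'
#' @param x binary vector (0/1 per 1-ms sample) or, with `times_ms`, the
#'   recording length in samples.
#' @param unit_id unit label.
#' @param fs sampling rate in Hz.
#' @param times_ms optional spike times in ms used to fill the vector.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(x, unit_id = "unit", fs = 1000, times_ms = NULL) {
  if (!is.null(times_ms)) {
    n <- as.integer(x)
    x <- integer(n)
    idx <- as.integer(round(times_ms)) + 1L
    stopifnot(all(idx >= 1L), all(idx <= n))
    x[unique(idx)] <- 1L
  }
  x <- as.integer(x)
  stopifnot(all(x %in% c(0L, 1L)))
  structure(list(unit_id = unit_id, x = x, fs = fs), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train '", x$unit_id, "': ", sum(x$x), " spikes over ",
      length(x$x) / x$fs, " s (", signif(sum(x$x) / length(x$x) * x$fs, 4),
      " spikes/s)\n", sep = "")
  invisible(x)
}

# Accept either a spike_train or a raw binary vector.
as_spike_vector <- function(s) {
  if (inherits(s, "spike_train")) s$x else {
    s <- as.integer(s); stopifnot(all(s %in% c(0L, 1L))); s
  }
}
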