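# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixture_env)) assign(name, fun(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 90-s meso recording with 20 MC trials (fixed movement duration so event
# timing is exactly known), plus filtered/normalized analytic signals.
fix_meso <- function() fixture("meso", function() {
  trials <- generate_trials("MC", 20,
                            movement_duration_law = list(dist = "uniform",
                                                         min = 500, max = 1500),
                            seed = 101)
  meso <- generate_meso_lfp(trials, max(90000, trial_span(trials) + 2000),
                            seed = 102)
  aL <- normalize_amplitude(filter_signal(meso$s_L, 28))
  aR <- normalize_amplitude(filter_signal(meso$s_R, 28))
  list(trials = trials, meso = meso, aL = aL, aR = aR,
       pd = phase_difference(aL, aR))
})

# A deterministic trial table with fixed durations.
fix_trials_fixed <- function(task = "MC", n = 8, seed = 1)
  generate_trials(task, n, list(dist = "fixed", value = 900), seed = seed)

# Build a binned_mapping directly from a support/rate pair (noiseless
# oracle inputs where the residual at the truth is exactly zero).
mk_mapping <- function(A, R, variable = "amplitude") {
  structure(list(variable = variable, A = A, R = R, n_bins = length(A),
                 P = 100, N = 100 * length(A), N_t = 100 * length(A),
                 fs = 1000),
            class = "binned_mapping")
}

# Random sigmoid parameter sets for ensemble tests.
random_sigmoid_pars <- function(n) {
  lapply(seq_len(n), function(i)
    c(p1 = stats::runif(1, 5, 30), p2 = stats::runif(1, -8, 8),
      p3 = stats::runif(1, 0.6, 1.6), p4 = stats::runif(1, 0.08, 0.5)))
}

# Grid-enumeration oracle for rank-order states.
grid_state_oracle <- function(pars, domain, n_grid = 1e4) {
  g <- seq(domain[1], domain[2], length.out = n_grid)
  rk <- apply(vapply(pars, function(p) F_S(g, p), numeric(n_grid)), 1,
              function(r) paste(order(-r, seq_along(r)), collapse = "/"))
  rle(rk)$values
}
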