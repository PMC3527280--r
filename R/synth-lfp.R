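# Synthetic meso- and array-scale LFP generation.
#
# Each hemisphere's meso signal is a 1/f^2 background plus an
# amplitude-modulated beta oscillation.  The envelope is a log-normal AR(1)
# process (time constant ~200 ms) multiplied by event-locked gain profiles
# (desynchronization after each go cue, rebound during reward).  The
# oscillation amplitude is calibrated so the Welch PSD of the summed signal
# peaks at the configured level at the configured frequency.  The right
# hemisphere shares the oscillator phase up to a slowly varying wrapped
# offset whose concentration emulates near-zero-lag inter-hemispheric
# coupling.  Array channels share the meso oscillation with a spatially
# correlated phase-jitter field calibrated (by inverting a numerically
# measured concentration-composition curve) so that pairwise phase-difference
# concentration follows a linear law in inter-electrode distance.

# Real Gaussian noise with an exact one-sided target PSD (synthesized in the
# frequency domain, so no estimation error enters the scaling).
shaped_noise <- function(n, fs, S) {
  nf <- n %/% 2L
  f <- seq_len(nf - 1L) * fs / n
  amp <- sqrt(n * fs * S(f) / 2)
  zk <- complex(real = stats::rnorm(nf - 1L), imaginary = stats::rnorm(nf - 1L)) / sqrt(2)
  X <- complex(length.out = n)
  X[2:nf] <- amp * zk
  X[n:(n - nf + 2L)] <- Conj(X[2:nf])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# One-sided PSD of the 1/f^2 background, anchored at `level_db`
# (10*log10(uV^2/Hz)) at `f0`, flattened below 0.5 Hz.
bg_psd_fun <- function(level_db, f0 = 28) {
  S0 <- 10^(level_db / 10)
  function(f) S0 * (f0 / pmax(f, 0.5))^2
}

# Raised-cosine spectral weight: 1 below f1, 0 above f2.
rc_lowpass_weight <- function(f, f1 = 12, f2 = 18) {
  w <- numeric(length(f))
  w[f <= f1] <- 1
  ramp <- f > f1 & f < f2
  w[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - f1) / (f2 - f1)))
  w
}

# Apply a symmetric spectral weight w(|f|) to a real series via the FFT.
apply_spectral_weight <- function(x, fs, wfun) {
  n <- length(x)
  f <- c(seq(0, n %/% 2), seq(-((n - 1L) %/% 2), -1)) * fs / n
  Re(stats::fft(stats::fft(x) * wfun(abs(f)), inverse = TRUE)) / n
}

# Shift a series by `lag` samples (positive = delay), replicating edges.
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(rep(x[1], lag), x[seq_len(n - lag)])
  else c(x[(-lag + 1L):n], rep(x[n], -lag))
}

# Event-locked multiplicative envelope gain: beta drops during movement and
# rises during reward delivery; edges smoothed with a Gaussian kernel.
event_gain_profile <- function(n, trials, desync) {
  g <- rep(1, n)
  if (is.null(trials) || is.null(desync)) return(g)
  for (i in seq_len(nrow(trials))) {
    mv <- seq(trials$t_go[i] + 1L, min(trials$t_target_enter[i], n))
    rw <- seq(trials$t_reward_on[i] + 1L, min(trials$t_reward_off[i], n))
    g[mv] <- desync$move_gain
    g[rw] <- desync$reward_gain
  }
  gaussian_smooth(g, desync$smooth_ms %||% 100)
}

#' Default meso-signal generator settings
#'
#' @return a list of tunable generator parameters: log-envelope standard
#'   deviation and AR(1) time constant, oscillator phase-jitter scale,
#'   inter-hemispheric von Mises concentration `kappa_lr` and offset time
#'   constant, background level relative to the spectral peak (dB), shared
#'   log-envelope weight between hemispheres, and the optional
#'   phase-difference gating of amplitudes (`pd_gate`).
#' @export
meso_defaults <- function() {
  list(env_sd_log = 0.4, env_tau_ms = 200,
       phase_jitter_sd = 0.25, phase_jitter_tau_ms = 500,
       kappa_lr = 2, delta_tau_ms = 300,
       bg_rel_db = 14, env_share = 0.4,
       pd_gate = NULL)
}

#' Generate paired meso-scale LFP signals
#'
#' Produces spatially averaged ("meso") left and right signals with a beta
#' spectral bump over a 1/f^2 background, go-cue-locked beta
#' desynchronization, reward-locked rebound, and inter-hemispheric
#' phase-difference concentration near zero lag.
#'
#' @param trials a `trial_table` (or `NULL` for event-free signals).
#' @param duration recording length in ms.
#' @param psd_peak_freq beta peak frequency in Hz.
#' @param psd_peak_level target Welch PSD level at the peak, in
#'   10*log10(uV^2/Hz).
#' @param desync_profile list with `move_gain`, `reward_gain`, `smooth_ms`,
#'   or `NULL` to disable event-locked envelope modulation.
#' @param seed integer RNG seed.
#' @param opts generator settings, see [meso_defaults()]; the optional
#'   element `pd_gate = list(lag_ms, gain, corr_mix)` makes hemispheric
#'   envelopes depend on the inter-hemispheric phase difference at a fixed
#'   lag (mean-amplitude gating via `gain`, amplitude-correlation gating via
#'   `corr_mix`).
#' @return object of class `meso_lfp`: list with numeric series `s_L`,
#'   `s_R` (uV), `fs`, `f0`, the `trials` table, the oscillation scale
#'   `alpha`, and a `components` list (envelopes, phases, phase offset
#'   `delta`, backgrounds, event gain) used by [generate_array_lfp()] and by
#'   oracle checks.
#' @export
generate_meso_lfp <- function(trials = NULL, duration = 300000,
                              psd_peak_freq = 28, psd_peak_level = -46,
                              desync_profile = list(move_gain = 0.45,
                                                    reward_gain = 1.3,
                                                    smooth_ms = 100),
                              seed = NULL, opts = meso_defaults()) {
  fs <- 1000
  n <- as.integer(duration)
  stopifnot(n > 10 * fs)
  if (!is.null(trials) && duration < trial_span(trials))
    stop("duration (", duration, " ms) shorter than the trial span (",
         trial_span(trials), " ms)")
  if (!is.null(seed)) set.seed(seed)
  o <- utils::modifyList(meso_defaults(), as.list(opts))
  f0 <- psd_peak_freq

  bgS <- bg_psd_fun(psd_peak_level - o$bg_rel_db, f0)
  bg_L <- shaped_noise(n, fs, bgS)
  bg_R <- shaped_noise(n, fs, bgS)

  # common oscillator phase + slow wrapped offset between hemispheres
  tt <- seq_len(n) / fs
  phi_L <- 2 * pi * f0 * tt + ar1_series(n, o$phase_jitter_sd,
                                         o$phase_jitter_tau_ms)
  sd_delta <- sqrt(-2 * log(vm_A(o$kappa_lr)))
  delta <- ar1_series(n, sd_delta, o$delta_tau_ms)
  phi_R <- phi_L - delta

  # hemispheric log-envelopes: own + shared components; optional gating by
  # the lagged phase difference
  x_com <- ar1_series(n, 1, o$env_tau_ms)
  x_L <- ar1_series(n, 1, o$env_tau_ms)
  x_R <- ar1_series(n, 1, o$env_tau_ms)
  w <- rep(o$env_share, n)
  gate_gain <- rep(1, n)
  if (!is.null(o$pd_gate)) {
    # positive lag: amplitudes follow the phase difference `lag` ms later
    gc <- cos(shift_series(delta, as.integer(o$pd_gate$lag_ms %||% 0)))
    if (!is.null(o$pd_gate$corr_mix))
      w <- pmin(pmax(o$env_share + o$pd_gate$corr_mix * gc, 0), 1)
    if (!is.null(o$pd_gate$gain))
      gate_gain <- pmax(1 + o$pd_gate$gain * gc, 0.05)
  }
  gain <- event_gain_profile(n, trials, desync_profile) * gate_gain
  E_L <- exp(o$env_sd_log * (sqrt(1 - w) * x_L + sqrt(w) * x_com)) * gain
  E_R <- exp(o$env_sd_log * (sqrt(1 - w) * x_R + sqrt(w) * x_com)) * gain
  E_L <- E_L / mean(E_L)
  E_R <- E_R / mean(E_R)

  osc_L <- E_L * cos(phi_L)
  osc_R <- E_R * cos(phi_R)

  # calibrate the oscillation scale so the summed Welch PSD hits the target
  # peak level
  P_target <- 10^(psd_peak_level / 10)
  psd_osc <- welch_psd(osc_L, fs)
  psd_bg <- welch_psd(bg_L, fs)
  band <- psd_osc$freq >= f0 - 5 & psd_osc$freq <= f0 + 5
  ipk <- which(band)[which.max(psd_osc$psd[band])]
  if (psd_bg$psd[ipk] >= P_target)
    stop("background level exceeds the requested spectral peak level")
  alpha <- sqrt((P_target - psd_bg$psd[ipk]) / psd_osc$psd[ipk])

  structure(list(s_L = bg_L + alpha * osc_L, s_R = bg_R + alpha * osc_R,
                 fs = fs, f0 = f0, trials = trials, alpha = alpha,
                 psd_peak_level = psd_peak_level,
                 components = list(E_L = E_L, E_R = E_R, phi_L = phi_L,
                                   phi_R = phi_R, delta = delta,
                                   bg_L = bg_L, bg_R = bg_R, gain = gain),
                 opts = o),
            class = "meso_lfp")
}

#' @export
print.meso_lfp <- function(x, ...) {
  cat("Meso LFP pair: ", length(x$s_L) / x$fs, " s at ", x$fs, " Hz, beta peak ",
      x$f0, " Hz @ ", x$psd_peak_level, " dB; ",
      if (is.null(x$trials)) "no trials" else paste(nrow(x$trials), "trials"),
      "\n", sep = "")
  invisible(x)
}

#' Electrode grid geometry
#'
#' @param nside electrodes per side.
#' @param pitch_mm inter-electrode spacing in mm.
#' @return matrix of channel coordinates (mm), one row per channel.
#' @export
electrode_grid <- function(nside = 8, pitch_mm = 0.5) {
  g <- expand.grid(x = seq_len(nside) - 1L, y = seq_len(nside) - 1L)
  as.matrix(g) * pitch_mm
}

# Build a zero-mean Gaussian field factor whose pairwise difference
# variances approximate the target matrix V: the covariance
# C = sigma^2 - V/2 is projected onto the PSD cone, and the injected
# variances are iteratively corrected by the realized-vs-required error
# (the target variogram need not be exactly embeddable).
build_phase_field <- function(V, n_iter = 40, floor = 0.005) {
  V_in <- V
  Cp <- NULL; Vr <- NULL
  for (it in seq_len(n_iter)) {
    s2 <- max(V_in) / 2
    C <- s2 - V_in / 2
    diag(C) <- s2
    eg <- eigen(C, symmetric = TRUE)
    Cp <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    Vr <- outer(diag(Cp), diag(Cp), "+") - 2 * Cp
    err <- V - Vr
    diag(err) <- 0
    V_in <- pmax(V_in + err, floor)
    diag(V_in) <- 0
  }
  eg <- eigen(Cp, symmetric = TRUE)
  list(L = eg$vectors %*% diag(sqrt(pmax(eg$values, 0))),
       V_realized = Vr)
}

# Synthesize array channels over the first n samples of the meso
# components: common oscillation with the per-channel jitter field, shared
# low-frequency background, independent channel noise.
synthesize_channels <- function(meso, hemi, L_field, shared_low, indep_S,
                                jitter_tau, n) {
  nch <- nrow(L_field)
  E <- meso$components[[paste0("E_", hemi)]][seq_len(n)]
  phi <- meso$components[[paste0("phi_", hemi)]][seq_len(n)]
  W <- matrix(0, n, nch)
  for (c_ in seq_len(nch)) W[, c_] <- ar1_series(n, 1, jitter_tau)
  M <- W %*% t(L_field)
  M <- meso$alpha * E * cos(M + phi)
  for (c_ in seq_len(nch))
    M[, c_] <- M[, c_] + shared_low[seq_len(n)] + shaped_noise(n, meso$fs, indep_S)
  M
}

# Measure per-pair mean resultant length of filtered phase differences.
measure_pair_R <- function(M, fs, f0) {
  nch <- ncol(M)
  U <- NULL; keep <- NULL
  for (c_ in seq_len(nch)) {
    a <- filter_signal(M[, c_], f0, fs = fs)
    if (is.null(U)) { keep <- a$valid; U <- matrix(0i, sum(keep), nch) }
    U[, c_] <- a$z[keep] / Mod(a$z[keep])
  }
  Mod(t(Conj(U)) %*% U) / nrow(U)
}

#' Generate a 64-channel array LFP from a meso signal
#'
#' Channels share the meso oscillation (common envelope and oscillator
#' phase) with a spatially correlated per-channel phase-jitter field, a
#' shared low-frequency background, and independent channel noise.  The
#' jitter field is calibrated numerically so that the von Mises
#' concentration of pairwise filtered phase differences follows
#' `kappa(d) = intercept + slope * d` in inter-electrode distance: starting
#' from the wrapped-Gaussian inversion of the concentration-composition
#' relation, short self-calibration syntheses measure the per-distance
#' attenuation of the realized concentration (filter smoothing, envelope
#' weighting, channel noise) and the injected variances are corrected and
#' re-measured over a few rounds.
#'
#' @param meso a `meso_lfp` object.
#' @param hemisphere `"L"` or `"R"`: which meso component the array samples.
#' @param grid channel coordinates in mm, see [electrode_grid()].
#' @param kappa_law numeric `c(intercept, slope)` of the concentration law
#'   per mm; must stay positive over all grid distances.
#' @param seed integer RNG seed.
#' @param jitter set `FALSE` for the degenerate diagnostic mode with no
#'   phase jitter and no channel noise (all channels identical).
#' @param indep_bg_rel_db independent channel-noise level at the beta peak,
#'   dB below the meso spectral peak.
#' @param jitter_tau_ms AR(1) time constant of the jitter field.
#' @param cal_dur_s,n_cal duration (s) and number of self-calibration
#'   rounds.
#' @return object of class `lfp_array`: list with `lfp` (samples x channels
#'   matrix, uV), `coords`, `fs`, `f0`, `hemisphere`, `pitch_mm` and a
#'   `calibration` record.
#' @export
generate_array_lfp <- function(meso, hemisphere = "L",
                               grid = electrode_grid(),
                               kappa_law = c(intercept = 2.67, slope = -0.4435),
                               seed = NULL, jitter = TRUE,
                               indep_bg_rel_db = 26, jitter_tau_ms = 400,
                               cal_dur_s = 90, n_cal = 3) {
  stopifnot(inherits(meso, "meso_lfp"), hemisphere %in% c("L", "R"))
  fs <- meso$fs
  n <- length(meso$s_L)
  nch <- nrow(grid)
  D <- as.matrix(stats::dist(grid))
  kap <- kappa_law[[1]] + kappa_law[[2]] * D
  if (jitter && any(kap[upper.tri(kap)] <= 0))
    stop("kappa_law is non-positive at the maximal inter-electrode distance")
  if (!is.null(seed)) set.seed(seed)

  bg <- meso$components[[paste0("bg_", hemisphere)]]
  indep_S0 <- bg_psd_fun(meso$psd_peak_level - indep_bg_rel_db, meso$f0)
  indep_S <- function(f) indep_S0(f) * (1 - rc_lowpass_weight(f)^2)
  shared_low <- apply_spectral_weight(bg, fs, rc_lowpass_weight)

  calib <- NULL
  if (jitter) {
    ut <- upper.tri(D)
    dcls <- round(D[ut], 6)
    R_target <- vm_A(kap[ut])
    # round 0: wrapped-Gaussian inversion of the composition relation
    att <- rep(1, length(R_target))
    n_cal_s <- min(as.integer(cal_dur_s * fs), n)
    V <- matrix(0, nch, nch)
    field <- NULL
    for (round_ in seq_len(n_cal + 1L)) {
      R_inj <- pmin(R_target / att, 0.999)
      V[ut] <- -2 * log(R_inj)
      V[lower.tri(V)] <- t(V)[lower.tri(V)]
      field <- build_phase_field(V)
      if (round_ > n_cal) break
      Mcal <- synthesize_channels(meso, hemisphere, field$L, shared_low,
                                  indep_S, jitter_tau_ms, n_cal_s)
      G <- measure_pair_R(Mcal, fs, meso$f0)
      # per-distance-class attenuation of the realized resultant length;
      # fixed-point update: next injection assumes the attenuation just
      # measured at the current operating point
      att_pair <- pmin(G[ut] / R_inj, 1)
      att_cls <- tapply(att_pair, dcls, mean)
      att <- pmax(as.numeric(att_cls[as.character(dcls)]), 0.05)
    }
    calib <- list(kappa_law = kappa_law,
                  mean_variance_distortion =
                    mean(abs(field$V_realized - V)[ut]),
                  n_cal = n_cal, cal_dur_s = cal_dur_s)
    M <- synthesize_channels(meso, hemisphere, field$L, shared_low,
                             indep_S, jitter_tau_ms, n)
  } else {
    E <- meso$components[[paste0("E_", hemisphere)]]
    phi <- meso$components[[paste0("phi_", hemisphere)]]
    M <- matrix(meso$alpha * E * cos(phi) + shared_low, n, nch)
  }
  structure(list(lfp = M, coords = grid, fs = fs, f0 = meso$f0,
                 hemisphere = hemisphere,
                 pitch_mm = stats::median(diff(sort(unique(grid[, 1])))),
                 calibration = calib),
            class = "lfp_array")
}

#' @export
print.lfp_array <- function(x, ...) {
  cat("LFP array: ", ncol(x$lfp), " channels x ", nrow(x$lfp) / x$fs,
      " s at ", x$fs, " Hz (hemisphere ", x$hemisphere, ", pitch ",
      x$pitch_mm, " mm)\n", sep = "")
  invisible(x)
}

#' Spatial average of an electrode array
#'
#' Per-sample arithmetic mean across channels — the meso-scale signal
#' comparable to a single ECoG macroelectrode.  Warns (and proceeds) if the
#' channel count is not 64.
#'
#' @param array an `lfp_array` or a samples x channels numeric matrix.
#' @return numeric meso signal.
#' @export
spatial_average <- function(array) {
  M <- if (inherits(array, "lfp_array")) array$lfp else as.matrix(array)
  if (ncol(M) != 64)
    warning("expected 64 channels, got ", ncol(M), "; averaging anyway")
  rowMeans(M)
}
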