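# Small shared numerical primitives.

#' Wrap angles to [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# von Mises mean resultant length A(kappa) = I1(kappa)/I0(kappa).
# Scaled Bessel ratios are stable for large kappa.
vm_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Exact inverse of A(kappa) by root finding; values of R at or above A(cap)
# are returned as the cap (near-degenerate concentration).
vm_A_inv <- function(R, cap = 50) {
  stopifnot(all(is.finite(R)), all(R >= 0), all(R <= 1))
  vapply(R, function(r) {
    if (r <= 0) return(0)
    if (r >= vm_A(cap)) return(cap)
    stats::uniroot(function(k) vm_A(k) - r, lower = 1e-10, upper = cap,
                   tol = 1e-10)$root
  }, numeric(1))
}

# von Mises sampler (Best & Fisher rejection scheme).
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(sign(u[3] - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

# Circular mean and mean resultant length of a sample of angles.
circ_mean_R <- function(theta) {
  z <- mean(exp(1i * theta))
  list(mu = Arg(z), R = Mod(z))
}

# Circular (Fisher-Lee) correlation coefficient between two angle series.
circ_cor <- function(a, b) {
  sa <- sin(a - circ_mean_R(a)$mu)
  sb <- sin(b - circ_mean_R(b)$mu)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# Linear FFT convolution of x with (possibly complex) kernel centred at index
# `half + 1`; returns a series aligned with x (zero phase). dt scales the
# discrete sum into an approximation of the continuous integral.
fft_convolve_centered <- function(x, kernel, half, dt = 1) {
  n <- length(x)
  m <- length(kernel)
  nf <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(kernel, rep(0, nf - m)))
  y <- stats::fft(X * K, inverse = TRUE) / nf
  y[(half + 1L):(half + n)] * dt
}

# Gaussian smoothing of a real series (reflective edge handling), sd in samples.
gaussian_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- ceiling(4 * sd)
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  y <- fft_convolve_centered(xp, k, half, dt = 1)
  Re(y[(half + 1L):(half + length(x))])
}

# AR(1) series with stationary standard deviation `sd` and time constant
# `tau` (in samples); initialized from the stationary distribution.
ar1_series <- function(n, sd, tau) {
  if (sd == 0) return(numeric(n))
  a <- exp(-1 / tau)
  e <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  e[1] <- stats::rnorm(1, sd = sd)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms (Hann window, 50% overlap), one-sided
#' density scaling so that white noise of variance `s^2` sampled at `fs`
#' has a flat density of `2 s^2 / fs` below Nyquist.
#'
#' @param x real-valued series.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @return a data.frame with columns `freq` (Hz) and `psd` (power per Hz, in
#'   the squared units of `x`).
#' @export
welch_psd <- function(x, fs, nperseg = 4096) {
  n <- length(x)
  stopifnot(n >= nperseg)
  step <- nperseg %/% 2L
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / nperseg)
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[seq_len(nf)])^2 / scale
    acc <- acc + P
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  data.frame(freq = seq(0, nperseg %/% 2L) * fs / nperseg, psd = psd)
}

#' Locate the spectral peak of a PSD within a band
#'
#' @param psd data.frame from [welch_psd()].
#' @param band numeric length-2 frequency band in Hz to search.
#' @return list with `freq` (Hz) and `level_db` (10*log10 of the density).
#' @export
psd_peak <- function(psd, band = c(10, 45)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  stopifnot(any(sel))
  i <- which.max(psd$psd[sel])
  f <- psd$freq[sel][i]
  list(freq = f, level_db = 10 * log10(psd$psd[sel][i]))
}
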