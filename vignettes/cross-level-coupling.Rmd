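---
title: "Cross-level coupling between spiking and the beta rhythm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-level coupling between spiking and the beta rhythm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(clcoupling)
```

## The scientific problem

Motor-cortical neurons do not respond only to "external" covariates such as
movement direction: their instantaneous firing probability also depends on
"internal" network state, summarized here by the sensorimotor beta rhythm
(a 10–45 Hz oscillation of the local field potential, LFP, with a spectral
bump near 28 Hz).  We call the statistical dependence between micro-scale
spiking and meso-/macro-scale oscillatory activity *cross-level coupling*
(CLC).  The package estimates phenomenological CLC models for individual
neurons —

* an **amplitude-to-rate** mapping: rate conditioned on the normalized beta
  envelope, fitted by the 4-parameter sigmoid
  $F_S(a) = p_1 + p_2\,\tanh\!\big((a - p_3)/(2 p_4)\big)$;
* a **phase-to-rate** mapping: rate conditioned on the instantaneous beta
  phase, fitted by the cosine $F_C(\theta) = p_1 + p_2\cos(\theta - p_3)$
  with depth $p_2 \ge 0$ and preferred phase $p_3$;
* a **phase-difference-to-rate** mapping in the wrapped phase difference
  between the left and right hemispheres, fitted by the von Mises-type
  curve $F_D(\varphi) = p_1 + p_2 \exp[p_3 \cos(\varphi - p_4)]$;
* the **joint beta-to-rate** model
  $F_B(a,\theta) = p_1 + p_2\tanh\!\big((a-p_3)/(2p_4)\big) +
  (p_5 a + p_6 a^2)\cos(\theta - p_7)$, whose quadratic weight
  $w_{\mathrm{AMP}}(a) = b_1 a + b_2 a^2$ expresses amplitude as a gain
  control on the phase preference;
* a **multivariate** model replacing the scalar conditioning variable by
  the vector of complex beta coefficients across an electrode array,
  through baseline and spike-triggered complex Gaussian distributions and
  their per-sample log-likelihood ratio $L$.

All estimators share one primitive: equal-count binning.  The conditioning
series and the binary 1-ms spike vector are truncated to the largest
multiple of the bin count, stably sorted by the conditioning value,
partitioned into bins holding exactly $P$ samples each, and summarized by
the per-bin mean support and the per-bin rate $R = (S_R/P)\sum x_S$.
Because bins are exactly equal-count, the count-weighted mean of bin rates
reproduces the truncated-data firing rate identically — a conservation law
the test suite asserts on every call.

Because the recordings behind these analyses are not publicly deposited,
the package pairs each estimator with a synthetic-data generator whose
ground truth is known exactly.  The generator is first-class, tested code:
every downstream claim about the estimators is demonstrated against it.

## Analytic-signal filtering

Band isolation uses a complex Gabor atom
$g(t) = 2^{1/4} e^{-s_0/4} \exp\!\big(-\pi t^2 e^{-s_0}\big)
\exp(i 2\pi v_0 t)$, parameterized by center frequency $v_0$ and the
log-scale duration parameter $s_0$.  Its temporal envelope has standard
deviation $\sigma_t = \sqrt{e^{s_0}/(2\pi)}$, and the Gaussian profile of
its *power* spectrum has standard deviation
$\sigma_f = 1/(2\sqrt{\pi}\, e^{s_0/2})$ — the amplitude-spectrum width
divided by $\sqrt 2$.  At the beta setting $s_0 = -5.075$, $v_0 = 28$ Hz
this gives $\sigma_f = 3.57$ Hz, which the test suite confirms by an
independent FFT route:

```{r gabor}
gabor_sigma_f(-5.075)
gabor_spectral_sd(28, -5.075)   # numerical kernel spectrum
```

Numerical choices: the convolution is FFT-based and zero-phase (kernel
centered); the kernel is truncated at $\pm 5$ temporal standard deviations,
which keeps the passband ripple of a stationary tone below $10^{-6}$
relative; samples within half a kernel length of either edge are masked
invalid, and the mask is honored by every downstream estimator.  Phase 0
marks the oscillation peak of the real part, $\pm\pi$ the trough; cycle
segmentation and "lag relative to trough" conversions anchor to this
convention.  Amplitude normalization divides by the grand mean over valid
samples *after* concatenating a task's recording blocks, so the mean
normalized amplitude is exactly 1.  Frequency banks are log-spaced with
constant relative bandwidth matched to the 3.57-Hz width at 28 Hz.

## The synthetic generator

`generate_trials()` emulates the delayed center-out task grammar: center
hold 500 ms (Manual Control, MC) or 100 ms (Brain Control, BC), target
hold 400/50 ms, 500-ms reward, movement durations from a configurable law
capped at the 10-s error limit, and targets cycling pseudo-randomly with
near-equal counts.

`generate_meso_lfp()` builds each hemisphere's meso signal as a $1/f^2$
background plus an amplitude-modulated 28-Hz oscillation.  Choices worth
knowing:

* **Envelope**: log-normal AR(1) (SD 0.4 log units, time constant 200 ms)
  multiplied by event-locked gains — 0.45 during movement, 1.3 during
  reward, smoothed by a 100-ms Gaussian.  This reproduces the qualitative
  event-related pattern (go-cue-locked desynchronization, reward rebound);
  no quantitative envelope law exists to copy, so these values are the
  package's own calibration.
* **Spectral calibration**: the oscillation scale is solved numerically so
  that the Welch PSD of the summed signal peaks at the configured level
  (default $-46$ in $10\log_{10}(\mu V^2/\mathrm{Hz})$) at the configured
  frequency.  The background sits 14 dB below the peak at 28 Hz: with much
  smaller separations the $1/f^2$ background exceeds the beta bump at the
  low edge of the beta band and in-band noise swamps both the event-locked
  desynchronization and the phase structure.
* **Inter-hemispheric coupling**: the right hemisphere shares the
  oscillator phase up to a slow wrapped-Gaussian offset whose stationary
  concentration is set through the von Mises relation
  ($\sigma^2 = -2\log A(\kappa)$, with $A = I_1/I_0$ inverted exactly).
  The *measured* concentration after filtering is attenuated by in-band
  noise and envelope weighting (configured $\kappa = 2$ yields measured
  $\hat\kappa \approx 0.7$), but the distribution remains clearly peaked
  near 0 — the zero-lag coupling the analysis expects.  An optional gate
  makes hemispheric envelopes depend on the phase difference at a fixed
  lag (mean-amplitude gain and/or envelope-mixing for amplitude
  correlations), for testing the lagged-conditioning analyses.
* Even **without** any gating, conditioned mean amplitude genuinely dips at
  extreme phase differences: when the envelope is low, measured phases are
  noisier, so large $|\hat\varphi|$ moments coincide with low amplitudes.
  Tests that want a true independence null therefore construct it from
  independent draws rather than from the generator.

`generate_array_lfp()` shares the meso oscillation across 64 channels with
a spatially correlated phase-jitter field plus a shared low-frequency
background and independent channel noise (26 dB below the spectral peak at
28 Hz), so the broadband spatial average still correlates > 0.95 with the
meso input while the beta band carries resolvable pairwise phase structure.
The field is calibrated so pairwise von Mises concentration follows
$\kappa(d) = 2.67 - 0.4435\,d$ (per mm).  Two technical points documented
here because they shape the results:

1. The variogram implied by that linear law is *not* exactly embeddable as
   a stationary Gaussian field on the 8×8 grid (it fails conditional
   negative-definiteness), so the field builder projects the implied
   covariance onto the positive-semidefinite cone and iteratively corrects
   the injected pairwise variances; the residual class-mean distortion is
   ~0.01 rad².
2. Filtering, envelope weighting and channel noise attenuate the realized
   concentration relative to the injected one, so the generator runs a few
   short self-calibration syntheses, measures the per-distance attenuation
   of the resultant length, and corrects the injection — the numerical
   inversion of the concentration-composition curve.  At 300 s the
   recovered law is within ±0.05 of the intercept and ±0.03 of the slope
   across seeds.

`generate_spikes()` composes rates additively — baseline, trial-stage
offsets, cosine direction tuning, $F_S$-shaped amplitude term,
$w_{\mathrm{AMP}}\cdot\cos$ phase term, optional von Mises
phase-difference term — clips at zero, and draws per-1-ms Bernoulli spikes
(error above 1000 spikes/s, where a 1-ms Bernoulli bin saturates).  Task
remapping redraws amplitude slopes (sign flips included) and shifts BC
preferred phases earlier by 0.8 rad.  The shift carries per-unit jitter
(SD 0.5 rad): a pure ensemble-wide rotation would be invisible to circular
correlation, whereas the empirical remapping phenomenon this emulates involves
idiosyncratic per-neuron changes on top of the systematic shift.

## Estimation choices

* **Fitting**: bounded Levenberg–Marquardt least squares on the binned
  rates with an 8-start sign/shift grid; width $p_4 \ge 10^{-3}$ so the
  sign of $p_2$ carries the direction class.  The sigmoid's inflection and
  width are additionally bounded to the scale of the observed support and
  the half-range to 3× the observed rate range: outside those bounds the
  curve is indistinguishable from a line over the data and $p_2/p_4$ run
  off along a flat ridge.  The cosine fit is exact linear least squares in
  $(p_1, p_2\cos p_3, p_2\sin p_3)$.
* **Joint-model identifiability**: $R_{\mathrm{PHASE}}$ is fixed as the
  unit-amplitude cosine, so $w_{\mathrm{AMP}}(a) = p_5 a + p_6 a^2$
  exactly ($b_1 = p_5$, $b_2 = p_6$) and
  $F_B = R_{\mathrm{AMP}} + w_{\mathrm{AMP}} R_{\mathrm{PHASE}}$ holds
  identically.  The exact symmetry $(p_5, p_6, p_7) \sim
  (-p_5, -p_6, p_7 + \pi)$ is resolved by requiring
  $w_{\mathrm{AMP}}(1) \ge 0$.  Over the realistic amplitude support $a$
  and $a^2$ are nearly collinear, so $p_5$ and $p_6$ individually are the
  least stable quantities; $w_{\mathrm{AMP}}$ evaluated on the support is
  what the data determine.
* **Binning defaults**: 25 bins for univariate mappings (the standard
  choice for this estimator); 8 amplitude × 16 phase bins for the joint matrix, keeping
  thousands of samples per cell at 300 s.  Joint cells require ≥ 100 samples.
* **Permutation test**: the statistic is the across-bin variance of binned
  rates (a documented package choice); the null rotates the
  spike vector circularly by ≥ 1 s, preserving autocorrelation;
  $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
  1000 rotations by default.  Type-I error is verified by simulation at
  $\alpha \in \{0.01, 0.05\}$ over 200 null units.
* **Split-half design**: halves are odd/even trials; the default
  amplitude-mapping comparison correlates the signed fitted rate change
  between amplitudes 0.6 and 1.6 across units, which is stable where raw
  $p_2$ is ridge-dominated.
* **Trial stages**: move-to-center = center-cue onset → center entry;
  move-to-target = go cue → target entry; reward = reward on → off (standard
  stage names for this task; the boundaries are this package's choice).
* **Rank-order states**: pairwise sigmoid crossovers are located by sign
  changes on a $10^4$-point grid refined by bisection, deduplicated within
  $10^{-4}$ amplitude units; states are enumerated over the 0.2–3 domain
  of normalized amplitude (roughly the 1st–99th percentile; the tails are
  data-starved), with rate ties broken by unit order.  The enumeration is
  verified against a brute-force grid-ranking oracle.
* **Cycle statistics**: beta cycles are trough-to-trough segments at the
  phase wraps; cycles touching masked samples are dropped; first-spiker
  fractions use only cycles where each unit fires exactly once, and
  same-bin coincidences are excluded and counted.
* **Multivariate model**: the augmented mean and covariance
  ($R_B = [[\Gamma, C], [\bar C, \bar\Gamma]]$) are estimated with a
  diagonal shrinkage $\lambda \cdot \mathrm{tr}(R_B)/2N$, default
  $\lambda = 10^{-4}$ (spike-triggered sample counts can be small; the
  source is silent on conditioning).  Log-densities are evaluated through
  the equivalent real $2N$-dimensional Gaussian via a Cholesky
  factorization — the two forms agree identically, which a test asserts to
  $10^{-8}$ against an independently built real-Gaussian oracle.
  Per-channel inputs are amplitude-normalized before model fitting — a
  package choice made for scale invariance across channels.
  Train/test splits follow trial parity.
* **Lag convention** for phase-difference conditioning: positive lag means
  the amplitude series runs later than the phase-difference series (the
  phase difference predicts future amplitudes).
* **Channel subsets and regularization**: the augmented covariance has
  $\sim 2N^2$ free parameters, so the spike-triggered model of a
  64-channel subset fitted on a few thousand spike samples overfits badly
  at the nominal $\lambda = 10^{-4}$ — held-out prediction *loses* range
  as channels are added.  At desk-scale durations the 64-channel analyses
  use $\lambda \approx 0.3$; with hours of data (the regime of chronic
  multi-session recordings) the nominal value suffices.  Relatedly, under the default
  concentration law the phase field remains correlated across the whole
  array ($\kappa > 0.4$ at 5 mm), so a 4-channel corner block can already
  infer most of any distributed coupling; demonstrating the growth of
  prediction range with channel count requires a locality-controlled
  array (steeper decay, e.g. $\kappa(d) = 2.67 - 0.52 d$) and a unit
  coupled to a distal channel group with a common preferred phase
  (clustered channels with evenly spread preferred phases cancel each
  other's modulation).

## What the tests do and do not show

Every quantitative claim in the test suite is made against the generator's
ground truth: parameter recovery for all four families at 300 s (bias
bounded by 5% of the parameter scale, with the Monte-Carlo standard error
of the bias accounted for; RMSE decreasing over 75/150/300 s), calibrated
permutation tests, oracle-checked state enumeration and log-densities, and
the qualitative orderings reported for real recordings (within-task >
cross-task stability, amplitude-gated phase depth and first-spiker
ordering, growing prediction range with channel count).  Problem sizes in
the routine suite are scaled for a desk machine: 60–300-s recordings,
ensembles of 5–12 units, and 200 simulated units for test calibration —
the sizes at which the Monte-Carlo assertions above are sharp.

The generator emulates the *statistical structure the analyses assume*:
stationary coupling within a task, additive rate composition, a single
common oscillator per hemisphere with smooth spatial phase jitter, and
Bernoulli spiking.  Real recordings violate several of these (refractory
structure, non-stationary coupling within sessions, spike-sorting noise,
non-Gaussian LFP transients), so green tests certify the estimators, not
the biology: population percentages and per-neuron values from the animal
datasets are not reproducible from synthetic data and are not targets.
Known limitations: the exact linear concentration-distance law is not
exactly realizable by any random field on the grid (see above), so it is
matched in per-distance-class mean; the movement-duration law is a
configurable stand-in (no canonical behavioral distribution exists); and
the measured inter-hemispheric concentration is a filtered, attenuated
version of the configured latent one.

## A worked example

```{r example, eval = FALSE}
trials <- generate_trials("MC", 30, seed = 1)
meso <- generate_meso_lfp(trials, duration = 150000, seed = 2)
beta <- normalize_amplitude(filter_signal(meso$s_L, v0 = 28))

gt <- unit_ground_truth("demo",
  MC = unit_params(r_baseline = 20, amp = c(p2 = -6, p3 = 1, p4 = 0.2),
                   phase = c(b1 = 3, b2 = 1, pref = 1)),
  BC = unit_params(r_baseline = 20, amp = c(p2 = 6, p3 = 1, p4 = 0.2),
                   phase = c(b1 = 3, b2 = 1, pref = 0.2)))
spikes <- generate_spikes(gt, "MC", beta, trials = trials, seed = 3)

fit <- clc_fit(beta, spikes, "amplitude")
fit
plot(fit)
permutation_test(beta, spikes, n_perm = 999, seed = 4)
```

The pipeline wrapper (`run_clc_pipeline()`) chains the stages —
simulate → filter → fit → states → predict → report — under one seeded
configuration and writes all artifacts (CSV/JSON, a markdown report, and
figures) into a run directory.
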