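# clcoupling

Cross-level coupling (CLC) analysis: how the spiking of individual motor-cortical
neurons depends on the amplitude, phase, inter-hemispheric phase difference and
multichannel spatial pattern of the sensorimotor beta rhythm (10–45 Hz, band-isolated
around a 28-Hz spectral peak), and how those dependencies remap between tasks.
It is written for electrophysiologists and computational neuroscientists who want
tested, ground-truth-validated implementations of these estimators.

## The models

Spike trains are 1-kHz binary vectors; the conditioning signals are complex
analytic series obtained by convolving LFPs with a Gabor atom
`g(t) = 2^(1/4) exp(-s0/4) exp(-pi t² e^(-s0)) exp(i 2π v0 t)`
(beta setting: `v0 = 28 Hz`, `s0 = -5.075`, power-spectrum width 3.57 Hz),
with amplitudes normalized to a grand mean of 1.  Rates conditioned on each
variable are estimated by equal-count binning (sort → truncate → partition;
every bin holds exactly `P` samples) and fitted by:

| mapping | model |
|---|---|
| amplitude-to-rate | `F_S(a) = p1 + p2 tanh((a - p3)/(2 p4))` |
| phase-to-rate | `F_C(θ) = p1 + p2 cos(θ - p3)`, `p2 ≥ 0` |
| phase-difference-to-rate | `F_D(φ) = p1 + p2 exp[p3 cos(φ - p4)]`, `p3 > 0` |
| joint beta-to-rate | `F_B(a,θ) = p1 + p2 tanh((a-p3)/(2p4)) + (p5 a + p6 a²) cos(θ - p7)` |

with `w_AMP(a) = p5·a + p6·a²` the quadratic gain of the phase preference, so
`F_B = R_AMP + w_AMP · R_PHASE` exactly.  Dependence is tested by a circular-shift
permutation test on the across-bin rate variance.  Ensemble consequences (sigmoid
crossovers, amplitude-indexed rank-order states, preferred-phase-to-lag timing,
first-spiker fractions within beta cycles) and a multivariate predictor (baseline
vs spike-triggered complex augmented-Gaussian models, log-likelihood-ratio-to-rate
calibration) complete the pipeline.  A calibrated synthetic generator — task trials,
meso LFPs with a −46 dB 28-Hz bump over a 1/f² background and event-locked
desynchronization, 64-channel arrays obeying the pairwise phase-concentration law
`κ(d) = 2.67 − 0.4435·d` (per mm), and Bernoulli spikes from the additive rate
model — provides ground truth for every estimator.

## A worked example

```r
library(clcoupling)

trials <- generate_trials("MC", 30, seed = 1)
meso   <- generate_meso_lfp(trials, duration = 150000, seed = 2)
beta   <- normalize_amplitude(filter_signal(meso$s_L, v0 = 28))

gt <- unit_ground_truth("demo",
  MC = unit_params(r_baseline = 20, amp = c(p2 = -6, p3 = 1, p4 = 0.2),
                   phase = c(b1 = 3, b2 = 1, pref = 1)),
  BC = unit_params(r_baseline = 20, amp = c(p2 = 6, p3 = 1, p4 = 0.2),
                   phase = c(b1 = 3, b2 = 1, pref = 0.2)))
spikes <- generate_spikes(gt, "MC", beta, trials = trials, seed = 3)

fit <- clc_fit(beta, spikes, "amplitude")
fit
#> CLC amplitude-to-rate fit (sigmoid)
#>       p1       p2       p3       p4 
#> 20.58400 -7.24580  0.94203  0.25782 
#> R-squared on binned rates: 0.8978
permutation_test(beta, spikes, n_perm = 999, seed = 4)
#> Circular-rotation permutation test: bin-rate variance = 23.57, p = 0.001 (999 rotations)
```

The fitted offset, signed half-range, inflection and width recover the generator's
(20, −6, 1, 0.2); the negative `p2` classifies the unit as decreasing its rate with
rising beta amplitude, and the permutation p-value sits at the floor `1/(n_perm+1)`,
as expected for a strongly coupled unit.  `plot(fit)` overlays the fitted sigmoid on
the 25 binned rates; `summary`, `coef`, `predict`, `residuals` and `simulate` behave
as for any fitted R model.  `run_clc_pipeline(config, out_dir)` chains
simulate → filter → fit → states → predict → report deterministically under one seed.

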