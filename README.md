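# sbiflow

Amortized simulation-based Bayesian inference (SBI) for simulators that
produce time-series waveforms, with the posterior diagnostics needed to
tell a well-identified parameter from an indeterminate one.

Mechanistic models of neural time series — membrane analogs, neocortical
column models generating MEG/EEG current dipoles — have no tractable
likelihood $p(x \mid \theta)$. `sbiflow` performs Bayesian inference on
such models from simulations alone: parameters $\theta_i$ are drawn from
a prior $p(\theta)$, waveforms $x_i$ are simulated, and a conditional
masked autoregressive flow $\Phi(\theta \mid x)$ is trained on the pairs
so that

$$\Phi(\theta \mid x) \;\approx\; p(\theta \mid x) \;\propto\; p(x \mid \theta)\, p(\theta).$$

The estimator is *amortized*: one trained flow can be conditioned on any
observation within the prior's support. The package is aimed at
modelers who need to know not just a best-fit parameter set but whether
the data can identify the parameters at all.

## What it provides

* **Simulators** — a built-in resistor-capacitor circuit driven by two
  square current pulses (`rc_simulator()`, exact piecewise-exponential
  fast path plus an adaptive-ODE cross-check), and a plugin contract +
  registry for external forward models.
* **Priors** — uniform unit-cube sampling with linear or log10
  ("exponential") mapping to physical ranges (`prior_preset()`,
  `unit_to_physical()`), YAML round-trip, shipped presets.
* **Summary statistics** — PCA loadings (`fit_pca()`), peak
  magnitude/timing (`peak_features()`), spectral band power in the
  0–13 / 13–30 / 30–50 / 50–80 Hz bands (`band_power()`), or the raw
  waveform; Gaussian observation-noise injection.
* **Inference** — a conditional masked autoregressive flow written in
  package R code (MADE stack, Adam, early stopping):
  `train_posterior()`, `posterior_sample()`, `posterior_log_density()`.
* **Diagnostics** — parameter recovery error
  (`parameter_recovery_error()`; the 2-Wasserstein distance to a point
  mass at the truth, on unit-normalized parameters), posterior
  predictive checks (`posterior_predictive_check()`), distribution
  overlap coefficients on a 50-per-dimension tensor grid
  (`overlap_coefficient()`), local diagnostic heatmap grids
  (`diagnostic_grid()`, `grid_slice()`) and pair-plot exports.
* **Workflow** — config-driven end-to-end orchestration with seeded,
  hashed, manifest-tracked artifacts (`run_workflow()`,
  `compare_observations()`), plus a thin CLI at `inst/cli/sbiflow.R`.

## Worked example: finding an indeterminacy in the RC circuit

The RC circuit `C dV/dt = (E - V)/R + I_e(t)` (C = 6, R = 1, E = 0,
time in ms) is driven by a positive pulse of magnitude `i_pos` at
80–100 ms and a negative pulse of magnitude `i_neg` shifted by
`latency`. At zero latency the pulses overlap, only the difference
`i_pos - i_neg` is identified, and the posterior must spread along a
line — a parameter indeterminacy the diagnostics should expose.

```r
library(sbiflow)

sim   <- rc_simulator()                 # default grid: [0, 250] ms, dt = 0.5
prior <- prior_preset("rc_circuit")     # I+, I- ~ U(0,1) mA; latency ~ U(-75,75) ms

dataset <- generate_dataset(sim, prior, list(scheme = "pca", k = 30),
                            n = 20000, noise_variance = 0.01, seed = 101)
post <- train_posterior(dataset, seed = 102)
print(post)
#> <posterior_approximation> 3-parameter flow conditioned on 30 'pca' features
#>   trained on 20000 simulations of 'rc_circuit'; val NLL -4.0059 after 162 epochs

# exemplar 1: overlapping pulses (net -0.2 mA) -- amplitudes indeterminate
x0 <- simulate_rc(0.1, 0.3, 0, sim$grid)
s0 <- posterior_sample(post, 1000, x0, seed = 103)
posterior_correlation(s0, "i_pos", "i_neg")$estimate
#> [1] 0.9901088

# exemplar 2: 37.5 ms latency -- amplitudes identified
x1 <- simulate_rc(0.3, 0.5, 37.5, sim$grid)
s1 <- posterior_sample(post, 1000, x1, seed = 104)
parameter_recovery_error(attr(s1, "unit"),
                         physical_to_unit(c(0.3, 0.5, 37.5), prior))
#>       i_pos       i_neg     latency
#> 0.019262957 0.017637431 0.005173416

# can the two waveforms be told apart? marginal overlap per parameter
overlap_coefficient(post, x0, x1, k = 1:3)
#> [1] 9.412133e-02 9.603091e-02 3.944179e-13
```

Read: conditioned on the zero-latency waveform the amplitude samples are
almost perfectly correlated (r = 0.99) — the flow has learned the ridge
of equivalent parameter pairs rather than collapsing to a point.
Conditioned on the offset-pulse waveform, all three parameters are
recovered tightly (recovery errors of ~0.02 on the normalized (0,1)
scale, where 0 is perfect and 1 is the worst possible). The overlap
coefficients show the two waveforms demand essentially disjoint latency
values (OVL ≈ 4e-13) while the amplitude marginals overlap slightly
(OVL ≈ 0.09).

The same pipeline runs end to end from a YAML config:

```sh
Rscript inst/cli/sbiflow.R run --config inst/extdata/config/rc_smoke.yaml
```

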