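# smadburst

Stochastic ensemble modeling and burst analysis of single-cell
TGF-β/SMAD signaling.

Live-cell recordings of the nuclear-to-cytoplasmic SMAD2 ratio show
transient *activity bursts* on an intermediate (100–300 min) time scale
whose number and height grow with the TGF-β dose while their duration
does not. `smadburst` is a toolbox for tracing such temporal noise to its
mechanistic source. It provides:

* **An ensemble pathway model** — 22 intracellular species per cell
  (receptor binding, internalization, endosomal traffic, SMAD
  phosphorylation/trimerization, nucleocytoplasmic shuttling, Hill-form
  feedback) coupled through one shared, depletable extracellular ligand
  pool, defined declaratively in a YAML file
  (`inst/extdata/smad_model.yaml`) so published parameterizations can be
  dropped in. The readout is
  `r = (y18 + 2 y19 + 3 y20 + y21) / (y10 + y11 + 2 y13 + 3 y14)`.
* **CIR parameter noise** — blocks of kinetic parameters follow
  Cox–Ingersoll–Ross dynamics
  `dp_j = θ_j (p0_j − p_j) dt + σ_j √p_j dB_j`, which stay non-negative,
  preserve the mean, have bounded variance, and a right-skewed
  (Gamma/log-normal-like) stationary law. Five biologically themed
  blocks (`receptor_ligand`, `internalization`, `endosomal_traffic`,
  `synthesis`, `degradation`) define competing noise-source hypotheses;
  an Ornstein–Uhlenbeck variant is included for contrast.
* **A strong-order-1.5 semi-implicit SDE solver** — theta-averaged
  (Crank–Nicolson-type) drift, Milstein and Itō–Taylor corrections from
  paired normal draws, per-cell adaptive Newton with a Schur-complement
  solve of the ligand/cell arrow system, two-regime step sizes
  (0.04 during stimulation, 0.6 elsewhere), zero-clipping, and per-cell
  failure flags. An empirical convergence harness with coupled Brownian
  increments verifies the order.
* **Automated burst detection** — Gaussian-hill trend removal,
  band-limited smoothing, peak calling with height and
  full-width-at-half-height duration, plus ROC-based tuning of all
  detection parameters on labeled synthetic benchmarks.
* **A burst-statistics objective** — 21 weighted relative-difference
  components (burst height/duration medians and SDs for indices 1–4,
  count mean/SD, failed-path rate, snapshot mean/SD) whose squared sum
  discriminates noise-source models, with an AIC re-normalization for
  ranking, a scatter-search fitter with common random numbers, dose
  prediction, and restimulation analysis with mixed (temporally
  stable + unstable noise) ensembles.
* **Synthetic data for everything** — control-like technical noise,
  burst-injected benchmarks with exact ground truth, and
  pseudo-populations with tunable burst features; a CSV loader accepts
  externally measured trajectory tables of the same shape.

## Worked example

```r
library(smadburst)

model <- smad_model()
noise <- noise_block(model, "internalization",
                     sigma = c(0.015, 0.06, 0.03), theta = 0.01)

# 48 cells, 24 h, 100 pM bolus, control-like technical noise added post hoc
sim <- run_simulation(model, noise, dose = 100, n_cells = 48, seed = 1,
                      control_noise = control_noise_spec())
sim
#> <smad_ensemble> 48 cells, 289 time points (0-1440 min), block 'internalization', 0 failed

cfg <- detection_config(height_threshold = 0.05, burst_bandwidth = 35,
                        trend_bandwidth = 180, duration_bounds = c(75, 430))
catalog <- detect_bursts(sim, cfg)
glance(catalog)
#> # A tibble: 1 × 5
#>   n_cells n_failed mean_count median_height median_duration
#>     <int>    <int>      <dbl>         <dbl>           <dbl>
#> 1      48        0       3.17         0.139            119.
```

Each cell shows on average 3.2 bursts over 24 h with median height 0.14
ratio units and median duration ~2 h — the intermediate-time-scale
fluctuations the framework is built to explain. Comparing the
deterministic comparator (control noise only) against this stochastic
population with the objective function:

```r
det <- run_simulation(model, "deterministic", dose = 100, n_cells = 48,
                      seed = 1, control_noise = control_noise_spec())
obj <- assemble_objective(population_summary(det, cfg),
                          population_summary(sim, cfg))
glance(obj)
#> # A tibble: 1 × 2
#>   scalar failed_rate
#>    <dbl>       <dbl>
#> 1   5.19           0
```

The scalar distance of 5.19 is dominated by the snapshot standard
deviation, burst count and burst-height components — the deterministic
model cannot produce the cross-cell variability and repeated bursts of
the stochastic one. `fit_block_model()` minimizes exactly this scalar
over a block's `(p0, σ, θ)` coefficients, `compare_models()` tabulates
the per-component errors and AIC ratios across blocks, `predict_dose()`
re-simulates fitted coefficients at new doses, and
`run_restimulation()` probes repeated-stimulation memory with
reduced-feedback, reduced-SMAD4 and merged-ensemble variants.

A thin command-line front end over the same functions is installed at
`inst/cli/smadburst.R` (subcommands `simulate`, `make-benchmark`,
`tune-detect`, `detect`, `objective`, `fit`, `compare`, `predict`,
`restim`).

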