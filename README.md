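# scalerp

Unmixing fixed-time and scaled-time components in continuous scalp EEG.

## What this solves, and for whom

EEG researchers studying timing, anticipation, or any task with variable
stimulus-to-response intervals face a double superposition problem:
event-locked ("fixed-time") responses overlap each other when intervals
are short, and some activity — e.g. the slow negativity spanning a timed
interval — stretches or compresses with the interval itself
("scaled-time") and so is smeared by conventional epoch averaging.

`scalerp` fits both families jointly by regression on the continuous
recording (the rERP framework), extended with one variable-duration
regressor block:

```
Y = X β + ε
```

- `Y`: continuous EEG at one sensor (µV).
- `X`: samples × predictors. Fixed components contribute stick-function
  blocks (one column per lag; a 1,000 ms window at 200 Hz is exactly
  200 columns). The scaled component contributes one shared block of
  `n_points` columns whose temporal support is stretched per trial with a
  box (area-averaging) resampling operator to span that trial's
  cue→response interval; its columns index elapsed fraction, not
  milliseconds.
- Estimation: penalized least squares,
  `min ‖Xβ − Y‖² + λ‖Lβ‖²`, with `L` a blockwise first-difference
  (smoothness) operator and λ chosen by 10-fold cross-validation over
  `{0.001, 0.01, 0, 1, 10, 100, 1000, 10000, 100000}`.

Around the estimator, the package provides the full validation toolkit:
a ground-truth simulator, VIF collinearity profiles, conventional epoch
ERPs with threshold rejection, fixed-only/scaled-only dataset
reconstruction, a temporal-scaling index, spatiotemporal cluster-based
sign-flip permutation tests, a PCA latency analysis with repeated-measures
ANOVA effect sizes (η²p, η²g), and a small CLI.

## Worked example

```r
library(scalerp)

# simulate the production-task world: 50 trials x {0.8, 1.65, 2.5} s at
# 200 Hz, then add AR(1) noise at signal-RMS parity
sim0 <- simulate_dataset(sim_config(noise_amplitude = 0, seed = 1),
                         n_channels = 4)
sim <- with_noise(sim0, signal_rms(sim0), noise_model = "ar1")

n <- ncol(sim$recording$data)
blocks <- list(
  build_fixed_block(sim$events, fixed_window("cue", -200, 800), n, 200),
  build_fixed_block(sim$events, fixed_window("response", -800, 200), n, 200),
  build_scaled_block(sim$events, scaled_spec(330), n))
design <- assemble_design(blocks, sim$recording)
design
#> <rerp_design> 98355 rows x 730 predictors (cue:200, response:200, scaled:330); 4 channels

cv <- cross_validate_lambda(design, channel = 1)
cv
#> <cv_report> mean MSE by lambda:
#>  0.001   0.01      0      1     10    100   1000  10000  1e+05
#> 8.9264 8.9264 8.9264 8.9263 8.9257 8.9246 8.9230 8.9801 9.4809
#> chosen lambda: 1000

fit <- fit_rerp(design, lambda = cv$chosen_lambda)
for (comp in c("cue", "response", "scaled"))
  cat(sprintf("%-8s recovery r = %.3f\n", comp,
      cor(get_waveform(fit, comp)[1, ], sim$shapes[[comp]]$waveform)))
#> cue      recovery r = 0.950
#> response recovery r = 0.994
#> scaled   recovery r = 0.975

um <- reconstruct_unmixed(design, fit)
i_sc <- scaling_index_of_variant(um, "scaled_only", sim$events, 200, n)
i_fx <- scaling_index_of_variant(um, "fixed_only",  sim$events, 200, n)
cat(sprintf("scaling index: scaled-only %.3f vs fixed-only %.3f\n",
            i_sc$index, i_fx$index))
#> scaling index: scaled-only 0.978 vs fixed-only 0.235

compute_vif(design)
#> <vif_profile> 730 predictors; median VIF 1.13; 0.0% >= 10
```

Reading the output: at noise equal in RMS to the signal, all three
waveforms are recovered with r ≥ 0.95 against the generating truth; the
mild smoothing penalty (λ = 1000) wins cross-validation; the scaling
index is near 1 only for the dataset variant that actually contains the
scaled component (0.978 vs 0.235), which is the unmixing working as
intended; and collinearity between fixed and scaled regressors is low
(VIF well under the conventional flag level of 10) because the simulated
intervals vary from trial to trial.

## Command line

```sh
Rscript inst/scripts/scalerp.R simulate --config cfg.json --out sim/
Rscript inst/scripts/scalerp.R fit --recording sim/recording.json \
    --events sim/events.tsv --config cfg.json --out fit/ --cv
```

Commands: `simulate`, `fit`, `vif`, `compare-models`, `scaling-index`,
`cluster-test`, `pca-latency`. Each writes its outputs together with a
config snapshot and a run log, so every result is reproducible from the
snapshot plus the seed. Recordings travel as a JSON sidecar + TSV matrix
(`write_recording()`/`read_recording()`; BrainVision `.vhdr` is also
read), events as BIDS-style TSV.

## Vignette

`vignettes/scaled-time-rerp.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the simulator does
and does not emulate, numerical choices, and known limitations.
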