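# emgdecode

Continuous 3-D hand-position decoding from surface electromyography
(EMG) with a recurrent fuzzy neural network (RFNN).

## The science

Surface EMG measures the electrical drive to muscle, which precedes the
mechanical movement it produces by an electromechanical delay of
roughly 50–100 ms. `emgdecode` exploits this lead to predict where the
hand will be a fixed time horizon (e.g. 250 ms) into the future, from
six channels of EMG alone. The decoder is a four-layer recurrent fuzzy
neural network:

- **Fuzzification**: Gaussian memberships
  `a[i,j] = exp(-(x_i - m_ij)^2 / sigma_ij^2)` partition each input.
- **Rule strength**: product T-norm `s_j = prod_i a[i,j]`.
- **Recurrence**: each rule keeps a first-order memory
  `u_j(t) = lambda_j * s_j(t) + (1 - lambda_j) * u_j(t-1)` with a
  learned ratio `lambda_j` in [0, 1] — this is what lets a fuzzy system
  capture the dynamics linking muscle activation to limb position.
- **Defuzzification**: normalized weighted sum
  `y_o = sum_j u_j w_jo / sum_j u_j`.

Centers, widths, recurrent ratios and weights are trained by gradient
descent (backpropagation truncated at depth 1); the rule base is
initialized by k-means clustering and adapted (prune/add) per epoch.
Inner loops are C++ (Rcpp) and are verified against plain-R scalar
oracles and finite differences in the test suite.

Around the network, the package implements the full offline pipeline:
linear-envelope preprocessing (detrend, median despike, rectify, 2 Hz
zero-phase Butterworth), windowed time-domain features (RMS, IEMG, MAV,
VAR, WL, SSI, SSC), movement segmentation, k-fold cross-validation with
NRMSE and Pearson correlation, condition comparisons, and
prediction-horizon sweeps. A seeded synthetic generator produces
synchronized EMG + kinematics for a two-task × two-speed
reach-and-return experiment, so every stage is testable without
human-subject recordings.

## Worked example

Simulate one trial, preprocess it, extract features, and cross-validate
a 250 ms-ahead decoder on its five movement cycles:

```r
library(emgdecode)

rec <- simulate_recording(task_profile("Task_1"), "quick", seed = 42L)
rec
#> <emg_recording> Task_1 / quick / trial 1: 35001 EMG samples @1000 Hz (6 ch), 2101 position samples @60 Hz

proc <- preprocess_recording(rec)
proc
#> <processed_recording> 35001 samples @1000 Hz: 6 envelope channels + 3 position axes

feats <- build_feature_matrix(proc)
feats
#> # A tibble: 699 × 13
#>    t_ms ch1_rms ch1_iemg ch2_rms ch2_iemg ch3_rms ch3_iemg ch4_rms ch4_iemg
#>   <dbl>   <dbl>    <dbl>   <dbl>    <dbl>   <dbl>    <dbl>   <dbl>    <dbl>
#> 1   100  0.0522     4.82   0.142     14.2  0.0489     4.73  0.0460     4.22
#> 2   150  0.0790     7.77   0.127     12.6  0.0674     6.67  0.0702     6.91
#> 3   200  0.0969     9.65   0.117     11.7  0.0818     8.15  0.0876     8.72
#> # ℹ 696 more rows

segs <- segment_cycles(proc)
cv <- cross_validate(segs, feature_spec(), rfnn_config(seed = 1L),
                     horizon_ms = 250, seed = 1L)
cv
#> # A tibble: 5 × 9
#>    fold  cc_x  cc_y  cc_z cc_mean nrmse_x nrmse_y nrmse_z nrmse_mean
#>   <int> <dbl> <dbl> <dbl>   <dbl>   <dbl>   <dbl>   <dbl>      <dbl>
#> 1     1 0.965 0.939 0.965   0.956  0.0934   0.114  0.0900     0.0992
#> 2     2 0.946 0.941 0.936   0.941  0.117    0.110  0.123      0.117
#> 3     3 0.974 0.949 0.972   0.965  0.0814   0.103  0.0830     0.0893
#> 4     4 0.965 0.943 0.960   0.956  0.0940   0.106  0.0948     0.0984
#> 5     5 0.975 0.951 0.976   0.967  0.0800   0.103  0.0780     0.0872

mean(cv$cc_mean)    # 0.957
mean(cv$nrmse_mean) # 0.098
```

A full multi-condition experiment runs through `run_pipeline()`:

```r
cfg <- pipeline_config(
  experiment = experiment_config(trials_per_condition = 3L, seed = 11L),
  horizon_ms = 250, seed = 5L
)
report <- run_pipeline(cfg)     # per-condition, per-fold CC and NRMSE
attr(report, "summary")         # condition-level means
```

## Command line

A thin CLI ships at `inst/cli/emg2kin.R` (after installation, at
`system.file("cli", "emg2kin.R", package = "emgdecode")`):

```sh
Rscript emg2kin.R simulate --trials 3 --seed 7 --out data/
Rscript emg2kin.R evaluate --data data/ --window-ms 100 --horizon-ms 250 --folds 5 --seed 7 --out results/
Rscript emg2kin.R sweep-horizon --data data/ --horizons 50,100,150,200,250,300 --out results/
Rscript emg2kin.R run --config config.yaml --seed 7 --out results/
```

Exit codes distinguish usage errors (2), data/schema errors (3) and
numeric/model errors (4).

## Reproducing results

`scripts/acceptance.R` runs the full study end-to-end against the
installed package and writes its main computed quantities to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

It simulates a reduced-scale experiment (2 tasks × 2 speeds × 3
trials), cross-validates the decoder in every condition at a 250 ms
horizon, sweeps the horizon at 100 and 300 ms, and fits a known
first-order teacher system as a recoverability check. All randomness
derives from `--seed`; rerunning with the same seed produces a
byte-identical JSON file. A full run takes about a minute on one CPU
core.

Note on horizon sweeps: with the default generator settings the
synthetic EMG leads the kinematics by ~75 ms and the envelope filtering
is zero-phase, so decoding error does not increase monotonically over
50–300 ms horizons — accuracy genuinely peaks near 300–400 ms before
degrading at longer horizons. See the methods vignette
(`vignettes/emg-decoding-methods.Rmd`) for details.

## License

MIT (see `LICENSE`).
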