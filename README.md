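# noiseceiling

Test-data noise ceilings for voxelwise fMRI encoding models.

## What problem this solves

Encoding models predict a voxel's fMRI response from a feature
representation of the stimulus, `beta = X P`, and are scored by how well
they predict responses estimated from held-out test data. Those test
responses are noisy, so even the *true* generating model cannot reach a
correlation of 1: measurement noise imposes an upper bound, the
**test-data noise ceiling**. A model correlating at 0.35 may be excellent
against a ceiling of 0.4 and poor against a ceiling of 0.9 — without the
ceiling the number is uninterpretable, and without a *good* ceiling
estimator the bound itself can be badly biased.

The package is for computational-neuroimaging researchers who fit
voxelwise (linearized) encoding or pRF-style models and want a defensible
per-voxel ceiling next to their accuracies.

## What it computes

Responses to single stimuli and their estimation variance come from a GLM
on the time series,

    beta_hat = (Phi' W Phi)^-1 Phi' W y,     V_hat = (Phi' W Phi)^-1 sigma^2,

with `W` the inverse noise covariance under one of three models —
i.i.d. (OLS), an AR(1) mixture fit by pooled REML (SPM convention), or
per-volume variances fit by Newton-Raphson REML (RobustWLS convention) —
or non-parametrically from the run-to-run variability of per-run
estimates, `V_ii = sum_r (beta_ir - mean_r)^2 / ((n_r - 1) n_r)`.

Three ceiling estimators, in correlation and R² units:

* **analytical** — `rho_NC = sqrt((s² - mean(V_ii)) / s²)`, with `s²` the
  response variance across stimuli; clipped to 0 when noise exceeds
  signal;
* **Monte Carlo** — same variance decomposition, evaluated by simulating
  noise-free and noise-contaminated responses and taking the median
  correlation (1000 samples); equivalent to the analytical form but ~10³
  times slower;
* **split-half** — correlate per-run mean responses of two disjoint run
  subsets, apply the Spearman-Brown correction `2r/(r+1)` to get the
  full-data reliability (= the R²-domain ceiling), square root for the
  correlation-domain ceiling.

Encoding models are fit by ridge regression and scored with correlation,
predictive R² and squared distance, including the exact identity linking
them. A simulation engine with known ground truth validates every
estimator under i.i.d., autocorrelated, non-stationary, and
run-variable-response noise.

## Worked example

Simulate the hardest diagnostic case — strongly autocorrelated noise —
and compare every estimator with the true ceiling computed from the
simulated ground truth:

```r
library(noiseceiling)
spec <- scenario_spec("ar1", snr = 1, ar_coefficient = 0.6,
                      n_voxels = 1000, n_replications = 8, seed = 11)
res <- run_scenario(spec)
res$summary
#>   estimator     method n  mean    p5   p95       sd true_mean true_p5 true_p95
#> 1       ols   analytic 8 0.977 0.977 0.978 0.000735     0.954   0.948    0.964
#> 2       ar1   analytic 8 0.970 0.968 0.971 0.001142     0.965   0.958    0.972
#> 3       nst   analytic 8 0.985 0.984 0.987 0.001239     0.913   0.901    0.928
#> 4       r2r   analytic 8 0.953 0.951 0.956 0.001819     0.955   0.948    0.963
#> 5        sh split_half 8 0.955 0.949 0.965 0.006349     0.955   0.948    0.963
```

Reading this: assuming white noise (`ols`) or only volume-wise variance
(`nst`) *overestimates* the ceiling — the mean estimate sits above the
[5, 95] band of the matched true ceiling (red flags for any model
comparison normalized by it). Modelling the autocorrelation (`ar1`), or
sidestepping covariance assumptions entirely via run-to-run variance
(`r2r`) or the split-half procedure (`sh`), stays inside the band; the
split-half estimator pays with the largest spread across replications.

On real data the entry points are `fit_gls()` / `fit_runwise()` on a
`ts_dataset()` plus a stimulus design (from an event table via
`design_from_events()`), followed by `analytic_nc()`,
`monte_carlo_nc()` or `split_half_nc()`, and
`noise_corrected_accuracy()` for reporting — always alongside the raw
accuracy and the ceiling, never instead of them.

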