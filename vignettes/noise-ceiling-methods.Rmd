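---
title: "Estimating the test-data noise ceiling of voxelwise encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the test-data noise ceiling of voxelwise encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiseceiling)
```

## The problem

Voxelwise encoding models predict a voxel's response to a stimulus from a
feature representation of that stimulus: `beta = X P`, where `X` (stimuli
x features) is the computational model and `P` is the voxel's population
receptive field. The model is scored by how well its predictions correlate
with responses estimated from *test* fMRI data. Those estimates are noisy,
so even the true generating model cannot reach a correlation of 1: the
measurement noise in the test data imposes an upper bound, the
*test-data noise ceiling*. Reporting model accuracy against this ceiling
separates "the model is wrong" from "the data are noisy".

This package implements the two-level estimation framework behind that
idea, three estimators of the ceiling, and a simulation engine that
validates each estimator against the truth it is supposed to recover.

## Two-level estimation

**Level 1 (time series).** Per voxel, single-stimulus response amplitudes
are estimated by generalized least squares,

\[
\hat\beta = (\Phi^{\mathsf T}\hat\Omega^{-1}\Phi)^{-1}
            \Phi^{\mathsf T}\hat\Omega^{-1} y ,
\qquad
\widehat V_{\hat\beta} = (\Phi^{\mathsf T}\hat\Omega^{-1}\Phi)^{-1}\hat\sigma^2 ,
\]

where `Phi` is the HRF-convolved event design and `Omega_hat` the assumed
noise covariance of the time series. Three parametrizations of
`Omega_hat` are provided:

* **identity** (`noise_identity()`, i.e. OLS);
* **AR(1) mixture** (`estimate_ar1_covariance()`): a two-component model,
  identity plus a fixed-autocorrelation basis with coefficient 0.2 (the
  SPM convention; the coefficient is a tunable argument), whose mixing
  weights are fit by Fisher-scoring REML to residual covariance blocks
  pooled over voxels — the covariance *shape* is shared by all voxels of a
  session, while each voxel keeps its own variance scale;
* **non-stationary / weighted** (`estimate_nonstationary_weights()`): a
  diagonal covariance with one variance per acquired volume (the
  RobustWLS convention), estimated by Newton–Raphson REML on
  log-variances.

A fourth, non-parametric route estimates the response and its variance
from the run structure alone: `fit_runwise()` fits the GLM separately per
run and `run_to_run_variance()` takes
\(\widehat V_{ii} = \sum_r (\hat\beta_{ir} - \bar{\hat\beta}_i)^2 /
((n_r - 1) n_r)\), the variance of the across-run mean. It makes no
assumption about the temporal structure of the noise and additionally
absorbs genuine run-to-run response variability (attention, adaptation,
fatigue) that no stimulus-feature model can predict.

**Level 2 (encoding).** `fit_ridge()` estimates the receptive field by
ridge regression (training responses mean-centered; the centering is
stored), `predict()` maps test features to predicted responses, and
`score_predictions()` computes the correlation `rho` (with unbiased
`n - 1` variances), the predictive `R^2`, the squared Euclidean distance
`D^2 = (n-1) s^2 (1 - R^2)`, the predicted-to-observed spread ratio
`gamma`, and the prediction mean bias. On centered test responses these
satisfy the exact identity
`R^2 = 2 rho gamma - gamma^2 - n/(n-1) bias^2 / s^2`
(`r2_identity_check()` verifies it per voxel), which is also how a
correlation-domain ceiling is transformed into the `R^2` domain: the true
model has `gamma = rho_NC` and zero bias, giving `r2_NC = rho_NC^2`
(`nc_to_r2()`).

## Three ceiling estimators

With `s2_hat` the variance of the estimated responses across stimuli and
`eps2 = mean(V_ii)` the average estimation variance:

* **Analytical** (`analytic_nc()`):
  \(\hat\rho_{NC} = \sqrt{(\hat\sigma^2_{\hat\beta} - \bar V)/
  \hat\sigma^2_{\hat\beta}}\). If the radicand is negative — the
  estimation noise exceeds the response variance, e.g. a voxel that does
  not respond — the ceiling is defined to be 0 and flagged `clipped`;
  chance level is then the best any model can do.
* **Monte Carlo** (`monte_carlo_nc()`): noise-free signals are drawn from
  `N(mean(beta_hat), s2_hat - eps2)`, noise `N(0, eps2)` is added, and the
  ceiling is the median correlation between the noise-free and the
  noise-contaminated draws (default 1000 samples, seeded and recorded).
  It has the same expected value as the analytical form — the tests and
  the acceptance script verify the agreement voxelwise — at roughly a
  thousandfold computational cost; it is retained as a cross-check and
  for users who want the sampling distribution.
* **Split-half** (`split_runs()` + `split_half_nc()`): the per-run
  estimates are averaged within two disjoint run subsets and correlated.
  The Spearman–Brown prophecy correction `rel = 2 rho / (rho + 1)` maps
  this half-data correlation to the *reliability* of the full data set,
  i.e. the expected correlation between two independent full
  replications. Because each independent measurement correlates with the
  noise-free signal by the ceiling itself, `rel` is the ceiling in the
  `R^2` domain, and the correlation-domain ceiling is `sqrt(rel)`. (The
  correction is frequently quoted without the square root; taking it
  literally as a correlation-domain value would systematically
  underestimate — the package's simulations show `2 rho/(rho+1)` landing
  exactly on the square of the matched true ceiling.) Negative split
  correlations clip to 0. With an odd number of runs the first half
  receives the extra run; the subsets used are recorded.

The run-to-run variance can be plugged into the analytical and Monte
Carlo estimators in place of a parametric `V`, giving the "R2R" ceiling.
`noise_corrected_accuracy()` divides a model's accuracy by the ceiling —
to be reported alongside, never instead of, the raw accuracy and the
ceiling, since identical ratios can hide order-of-magnitude differences
in effect size.

## The simulation engine

`scenario_spec()` fixes the study conditions; its defaults are the
conditions all validation results refer to: 126 training + 42 test
stimuli in 128 standard-normal features, receptive fields drawn standard
normal, one presentation of every stimulus per run in 6 fast
event-related runs (TR 2.6 s, inter-stimulus jitter drawn uniformly from
2–4 TRs, seeded), 1000 voxels sharing the noise covariance structure,
100 replications. Responses are rescaled per voxel so the noiseless time
series `Phi beta` has unit variance; SNR is that signal variance divided
by the noise variance.

Four noise scenarios: **iid** white Gaussian noise; **ar1** an AR(1)
recursion at a requested lag-1 coefficient (generated per run with a
100-volume burn-in, realized variance rescaled to the requested SNR);
**nonstationary** white noise in which a seeded random 5% of volumes is
multiplied by a factor — fixed per simulation by default, since the
factor is the condition axis of the corresponding experiment; a
per-volume uniform draw over `[1, factor]` is available as
`nst_draw = "uniform"`; **ar1_run_effects** AR(0.25) noise plus a
run-specific standard-normal response component. For that last scenario
the proportion between the run-common and run-specific variance is
calibrated in closed form so the expected correlation between the mean
responses of the two half-experiments equals a target (default 0.6): for
balanced halves of `n_h` runs, `V_run = V_common n_h (1 - t)/t`; with an
odd run count a root search on the exact expression is used instead.
Only the run-common component counts as signal in the SNR.

Because the generating responses are known, the *true* ceiling of any
estimation route is just `true_noise_ceiling()` — the correlation between
that route's `beta_hat` and the run-common `beta` — and it differs by
route: noisier estimators (OLS under autocorrelation, anything under
spikes) have genuinely lower ceilings. `run_scenario()` replicates the
whole pipeline, warm-starting the AR REML across replications, and
tabulates every estimator next to its matched truth with means and
[5, 95] percentile bands; per-replication failures are logged and
counted, never dropped silently.

What the generator deliberately leaves out: physiological noise
(cardiac/respiratory), spatial correlation between voxels, drift and
motion confounds, and slice-timing effects. Passing validation therefore
demonstrates correctness of the estimators under their stated
assumptions, not robustness to everything real 7T data contains.

## Numerical choices

* GLS is solved by per-run whitening (Cholesky of the run covariance,
  shared across equal-length runs) followed by a QR solve — never by
  explicit inversion of the full covariance. Residual degrees of freedom
  are `T - rank` of the whitened model, the trace of its
  residual-forming matrix.
* The AR-mixture REML uses Fisher scoring on pooled per-run residual
  second-moment blocks, with the fixed effects projected out per run
  (consistent with the per-run residuals), a moment-matched start
  (lag-0 and lag-1), step halving to preserve positive definiteness, and
  convergence at a relative hyperparameter change below 1e-6 within 64
  iterations; non-convergence is an error carrying the iteration trace.
  Noise covariance is block-diagonal across runs — cross-run covariance
  is fixed at zero.
* The two-component basis with a fixed 0.2 autocorrelation cannot
  represent strong AR(1) noise exactly; its restricted-likelihood
  optimum has an implied lag-1 below the generating value (about 0.34
  for a generating 0.4 — the tests pin this against an independent
  `optim` oracle). What matters downstream is the implied estimation
  variance, and the validation scenarios show the resulting ceiling is
  unbiased up to high autocorrelation.
* The per-volume REML is Newton–Raphson on log-variances with a diagonal
  Fisher approximation, per-coordinate step damping against oscillation,
  a leverage-corrected start (`diag(S)/(1 - h)`), and a variance floor of
  0.01 times the mean variance. The floor never binds under white or
  spiked noise; under strongly autocorrelated noise (a misspecified
  regime for a diagonal model) the unconstrained optimum drives some
  variances to zero, and the floor keeps the weighted fit
  non-degenerate. Weights are returned normalized to mean 1.
* Entries of the AR basis below 1e-8, and entries of covariance inverses
  below 1e-30, are zeroed. They are mathematically negligible at double
  precision, and letting exponentially decaying fill-in drift into
  subnormal floats slows dense linear algebra by an order of magnitude.
* Ridge regression is solved through the SVD of the feature matrix;
  `lambda = 0` with a numerically rank-deficient matrix is an error
  suggesting regularization. `lambda` is treated as an experimental
  factor (default grid `10^-2 ... 10^4`); no automatic cross-validation
  is performed.

## Design choices that were genuinely open

* **HRF**: only "canonical" is specified by the estimation framework;
  the double-gamma with response peak ~5 s, undershoot ~16 s and
  peak/undershoot ratio 6, sampled at the TR, is used for comparability
  with SPM-style analyses. Event schedules (random stimulus order, jitter
  set) are regenerated per seed.
* **Whole-series vs run-wise fits**: parametric estimators use the
  whole-series fit; the run-to-run and split-half routes necessarily use
  per-run fits combined by averaging. Both are recorded in
  `estimator_kind`. For balanced noiseless designs the two coincide.
* **Split rule**: `odd_even` is the default (balanced across session
  time); `first_second` matches the convention of splitting a session
  into its first and second half; explicit subsets are validated for
  disjointness.
* **Ceiling stimulus set**: scenario summaries compute ceilings over the
  full simulated stimulus set (more stable); the encoding experiment
  computes them on its test set, where the ceiling conceptually lives.
* **Pooling**: covariance estimation pools all simulated voxels (the
  `voxel_pool` argument accepts any subset for sessions where pooling
  everything is too expensive).
* **Sample-size experiment**: the regularization study operates directly
  at the response level (`beta_hat = beta + noise`, estimation variance
  known to the ceiling), which is the regime the two-level framework
  reduces to after level 1 and keeps the experiment tractable at
  training sizes up to 1260 stimuli.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run the full design (168
stimuli, 6 runs, 1000 voxels) with replication counts chosen per check —
50 per noise level for the unbiasedness study, 8–12 for the structured
noise scenarios, 40 for the regularization study, 1000 Monte Carlo
samples throughout. `reproduce_figures(scale = 1)` restores 100
replications everywhere.

## Worked example

```{r example, eval = FALSE}
spec <- scenario_spec("ar1", snr = 1, ar_coefficient = 0.6,
                      n_voxels = 1000, n_replications = 8, seed = 11)
res <- run_scenario(spec)
res$summary
```

The identity-covariance estimator overestimates its ceiling under
autocorrelated noise, the AR(1), run-to-run and split-half estimators
stay inside the true ceiling's [5, 95] band, and the split-half estimator
shows the largest replication-to-replication spread — the three headline
behaviours the acceptance suite asserts.

## Known limitations

Missing or censored volumes are not supported (explicit error). The
combined AR(1)-plus-non-stationary covariance is not implemented; the two
models are alternatives. Group-level and representational-similarity
ceilings are out of scope, as are ceilings conditioned on training-set
size or on the regularization path. The split-half and run-to-run routes
need at least two (preferably more) runs per stimulus; with few runs the
run-to-run variance is itself noisy, which widens the ceiling's spread.
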