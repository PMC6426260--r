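# Shared fixtures: simulations are expensive, so heavily reused ones are
# built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small i.i.d. experiment, 300 voxels (pooled-covariance tests at mild cost)
fx_iid <- function() fx_get("iid", function() {
  spec <- scenario_spec("iid", snr = 1, n_voxels = 300, n_replications = 1,
                        seed = 101)
  simulate_experiment(spec)
})

# AR(1) lag 0.4 experiment, 1000 voxels, with its fitted covariance model
fx_ar <- function() fx_get("ar", function() {
  spec <- scenario_spec("ar1", snr = 1, ar_coefficient = 0.4, n_voxels = 1000,
                        n_replications = 1, seed = 102)
  sim <- simulate_experiment(spec)
  sim$S_blocks <- noiseceiling:::pooled_residual_blocks(sim$data, sim$design)
  sim$ar_model <- estimate_ar1_covariance(sim$data, sim$design,
                                          residual_blocks = sim$S_blocks)
  sim
})

# non-stationary experiment (5% volumes scaled by 3), 500 voxels, with weights
fx_nst <- function() fx_get("nst", function() {
  spec <- scenario_spec("nonstationary", snr = 1, nst_factor = 3,
                        n_voxels = 500, n_replications = 1, seed = 103)
  sim <- simulate_experiment(spec)
  sim$nst_model <- estimate_nonstationary_weights(sim$data, sim$design)
  sim
})

# single-regressor designs for hand-computed GLM examples
const_design <- function(n, runs = rep(1L, n)) {
  structure(list(Phi = matrix(1, n, 1), run_index = runs,
                 n_stimuli = 1L, n_runs = length(unique(runs)),
                 tr_seconds = 1, run_length_tr = n, events = NULL),
            class = "stim_design")
}

# response estimate built directly from numbers (bypassing the GLM)
make_estimate <- function(beta_hat, var_diag, kind = "identity",
                          beta_by_run = NULL, n_runs = 1L) {
  noiseceiling:::new_response_estimate(
    beta_hat, var_diag, sigma2 = rep(NA_real_, ncol(as.matrix(beta_hat))),
    estimator_kind = kind, variance_source = kind,
    n_runs = n_runs, beta_by_run = beta_by_run)
}

# cache used by the acceptance suite (scenario reused across criteria)
fx_acceptance_iid <- function() fx_get("acc_iid", function() {
  lapply(c(1, 10), function(nv) {
    spec <- scenario_spec("iid", snr = 1 / nv, n_voxels = 1000,
                          n_replications = 50, seed = 301 + round(nv))
    run_scenario(spec)
  })
})
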