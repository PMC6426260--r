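#' @title Simulation engine with known ground truth
#' @description Generates fMRI time series from a linear encoding model
#'   (responses = features x receptive field) under four noise scenarios --
#'   i.i.d. Gaussian, AR(1), non-stationary (spiked volumes), and AR(1) with
#'   run-to-run response variability -- and validates every noise-ceiling
#'   estimator against the true ceiling computable from the simulated truth.
#' @name simulate
NULL

#' Specify a simulation scenario
#'
#' Defaults mirror the reference experimental design: 126 training + 42 test
#' stimuli represented in 128 model features, presented once per run in 6
#' fast event-related runs (TR 2.6 s, inter-stimulus jitter of 2-4 TRs),
#' 1000 voxels sharing the noise covariance structure, 100 replications.
#'
#' @param scenario One of `"iid"`, `"ar1"`, `"nonstationary"`,
#'   `"ar1_run_effects"`.
#' @param snr Ratio of noiseless-signal variance to noise variance of the
#'   time series (for run-effects scenarios, only the run-common response
#'   counts as signal).  Must be positive.
#' @param ar_coefficient Lag-1 autocorrelation of the generated noise, in
#'   `[0, 1)`.  Default 0.25 for the run-effects scenario.
#' @param nst_factor Non-stationarity scaling factor (`>= 1`) applied to the
#'   noise of the affected volumes.
#' @param nst_fraction Fraction of volumes affected (default 0.05).
#' @param nst_draw `"fixed"`: affected volumes are scaled by `nst_factor`
#'   exactly; `"uniform"`: per-volume factors drawn uniformly from
#'   `[1, nst_factor]`.
#' @param target_split_half Expected correlation between the mean responses
#'   of the two half-experiments in the run-effects scenario (default 0.6).
#' @param n_voxels,n_runs,n_stimuli_train,n_stimuli_test,n_features,n_replications
#'   Problem sizes.
#' @param tr_seconds,isi_jitter Acquisition timing passed to
#'   [make_event_design()].
#' @param seed Master seed; all randomness in the scenario flows from it.
#' @return A validated `"scenario_spec"` list.
#' @export
scenario_spec <- function(scenario = c("iid", "ar1", "nonstationary", "ar1_run_effects"),
                          snr = 1,
                          ar_coefficient = NULL,
                          nst_factor = 1,
                          nst_fraction = 0.05,
                          nst_draw = c("fixed", "uniform"),
                          target_split_half = 0.6,
                          n_voxels = 1000,
                          n_runs = 6,
                          n_stimuli_train = 126,
                          n_stimuli_test = 42,
                          n_features = 128,
                          n_replications = 100,
                          tr_seconds = 2.6,
                          isi_jitter = c(2, 3, 4),
                          seed = 1) {
  scenario <- match.arg(scenario)
  nst_draw <- match.arg(nst_draw)
  ar_coefficient <- ar_coefficient %||%
    switch(scenario, ar1 = 0.25, ar1_run_effects = 0.25, 0)
  if (snr <= 0) stop("snr must be positive")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1) for a stationary AR(1) process")
  if (nst_factor < 1) stop("nst_factor must be >= 1")
  if (nst_fraction < 0 || nst_fraction > 1) stop("nst_fraction must lie in [0, 1]")
  if (scenario == "ar1_run_effects" &&
      (target_split_half <= 0 || target_split_half >= 1))
    stop("target_split_half must lie strictly between 0 and 1")
  stopifnot(n_voxels >= 1, n_runs >= 1, n_stimuli_train >= 1, n_stimuli_test >= 0,
            n_features >= 1, n_replications >= 1)
  structure(list(
    scenario = scenario, snr = snr, ar_coefficient = ar_coefficient,
    nst_factor = nst_factor, nst_fraction = nst_fraction, nst_draw = nst_draw,
    target_split_half = target_split_half,
    n_voxels = as.integer(n_voxels), n_runs = as.integer(n_runs),
    n_stimuli_train = as.integer(n_stimuli_train),
    n_stimuli_test = as.integer(n_stimuli_test),
    n_features = as.integer(n_features),
    n_replications = as.integer(n_replications),
    tr_seconds = tr_seconds, isi_jitter = as.integer(isi_jitter),
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': SNR %.3g, %d voxels, %d runs, %d+%d stimuli, %d features, %d replication(s), seed %d\n",
              x$scenario, x$snr, x$n_voxels, x$n_runs, x$n_stimuli_train,
              x$n_stimuli_test, x$n_features, x$n_replications, x$seed))
  invisible(x)
}

#' Draw a population receptive field
#'
#' Weights are i.i.d. standard normal, one vector per voxel.
#'
#' @param n_features Number of model features (`>= 1`).
#' @param seed RNG seed.
#' @param n_voxels Number of voxels (columns).
#' @return `n_features x n_voxels` matrix.
#' @export
gen_prf <- function(n_features, seed = NULL, n_voxels = 1L) {
  if (n_features < 1) stop("n_features must be at least 1")
  with_seed(seed, matrix(stats::rnorm(n_features * n_voxels), n_features, n_voxels))
}

#' Generate time-series noise under a scenario
#'
#' Noise is generated independently per run.  `iid`: white Gaussian with
#' variance `signal_variance / snr`.  `ar1`: an AR(1) recursion with the
#' requested lag-1 coefficient, rescaled per voxel so the realized noise
#' variance matches the requested SNR.  `nonstationary`: white noise with a
#' seeded random subset of volumes multiplied by the non-stationarity
#' factor.  The `ar1_run_effects` scenario uses the `ar1` noise generator.
#'
#' @param spec A `"scenario_spec"`.
#' @param run_index Per-volume run labels for the series to generate.
#' @param signal_variance Noiseless-signal variance defining the SNR
#'   (scalar, or one value per voxel).
#' @param n_voxels Number of voxels (columns).
#' @param seed RNG seed.
#' @return Time points x voxels noise matrix.  For the non-stationary
#'   scenario, the affected volumes are recorded in
#'   `attr(, "scaled_volumes")` and their factors in `attr(, "factors")`.
#' @export
gen_noise <- function(spec, run_index, signal_variance = 1, n_voxels = spec$n_voxels,
                      seed = NULL) {
  if (spec$ar_coefficient >= 1) stop("AR coefficient >= 1: process is not stationary")
  blocks <- run_blocks(run_index)
  Tn <- length(run_index)
  target_var <- signal_variance / spec$snr
  kind <- switch(spec$scenario, iid = "iid", nonstationary = "nst", "ar1")
  if (kind == "ar1" && spec$ar_coefficient == 0) kind <- "iid"
  with_seed(seed, {
    if (kind == "iid") {
      noise <- matrix(stats::rnorm(Tn * n_voxels), Tn, n_voxels)
      noise <- sweep(noise, 2L, sqrt(target_var), "*")
    } else if (kind == "ar1") {
      noise <- matrix(0, Tn, n_voxels)
      burn <- 100L
      a <- spec$ar_coefficient
      for (b in blocks) {
        e <- matrix(stats::rnorm((length(b) + burn) * n_voxels), ncol = n_voxels)
        for (t in 2:nrow(e)) e[t, ] <- e[t, ] + a * e[t - 1L, ]
        noise[b, ] <- e[(burn + 1):nrow(e), , drop = FALSE]
      }
      # rescale so the realized variance matches the requested SNR
      noise <- sweep(noise, 2L, sqrt(target_var) / col_sd(noise), "*")
    } else {
      noise <- matrix(stats::rnorm(Tn * n_voxels), Tn, n_voxels)
      noise <- sweep(noise, 2L, sqrt(target_var), "*")
      scaled <- unlist(lapply(blocks, function(b)
        sort(sample(b, floor(spec$nst_fraction * length(b))))))
      factors <- if (spec$nst_draw == "fixed") {
        rep(spec$nst_factor, length(scaled))
      } else {
        stats::runif(length(scaled), 1, spec$nst_factor)
      }
      noise[scaled, ] <- noise[scaled, , drop = FALSE] * factors
      attr(noise, "scaled_volumes") <- scaled
      attr(noise, "factors") <- factors
    }
    noise
  })
}

#' Calibrate run-to-run response variability to a split-half target
#'
#' The per-run response of a stimulus is the sum of a component common to
#' all runs (variance `common_variance` across stimuli) and a zero-mean
#' Gaussian run-specific deviation.  The deviation variance is chosen so
#' that the expected correlation between the mean responses of the two
#' half-experiments equals `target_split_half`.  For balanced halves
#' (`n_runs` even, halves of `n_h = n_runs / 2` runs) the closed form is
#' `run_variance = common_variance * n_h * (1 - t) / t`; for an odd number
#' of runs the variance is found by root search on the exact half-size
#' expression.
#'
#' @param n_stimuli Number of stimuli.
#' @param n_runs Number of runs.
#' @param target_split_half Target expected half-vs-half correlation,
#'   strictly inside `(0, 1)`.
#' @param seed RNG seed for the drawn deviations.
#' @param common_variance Variance of the run-common responses across
#'   stimuli (default 1).
#' @return List with `run_effects` (`n_stimuli x n_runs` deviations),
#'   `run_variance`, `proportion` (common / total variance) and
#'   `calibration` (`"analytic"` or `"search"`).
#' @export
gen_run_effects <- function(n_stimuli, n_runs, target_split_half, seed = NULL,
                            common_variance = 1) {
  if (target_split_half >= 1 || target_split_half <= 0)
    stop("target_split_half must lie strictly between 0 and 1 (1 is unattainable with run-specific variance)")
  if (n_runs < 2L) stop("run effects need at least 2 runs")
  t <- target_split_half
  if (n_runs %% 2L == 0L) {
    nh <- n_runs / 2
    run_variance <- common_variance * nh * (1 - t) / t
    calibration <- "analytic"
  } else {
    n1 <- ceiling(n_runs / 2); n2 <- n_runs - n1
    f <- function(vr) common_variance /
      sqrt((common_variance + vr / n1) * (common_variance + vr / n2)) - t
    run_variance <- stats::uniroot(f, c(1e-12, 1e6 * common_variance))$root
    calibration <- "search"
  }
  run_effects <- with_seed(seed,
    matrix(stats::rnorm(n_stimuli * n_runs, sd = sqrt(run_variance)),
           n_stimuli, n_runs))
  list(run_effects = run_effects, run_variance = run_variance,
       proportion = common_variance / (common_variance + run_variance),
       calibration = calibration)
}

#' Simulate one replication of an experiment
#'
#' Draws a feature matrix and per-voxel receptive fields, forms the true
#' responses `beta = X P` (rescaled per voxel so the noiseless time series
#' `Phi beta` has unit variance), adds run-specific response deviations in
#' the run-effects scenario, and superimposes scenario noise at the
#' requested SNR.
#'
#' @param spec A `"scenario_spec"`.
#' @param design Optional `"stim_design"` to reuse across replications;
#'   generated from the spec seed when `NULL`.
#' @param seed Replication seed (defaults to the spec seed).
#' @return List with `data` (a [ts_dataset()]), `design`, `truth` (true
#'   responses `beta_true`, optional `beta_by_run`, `prf_true`,
#'   `feature_matrix`, train/test indices, run-effect calibration) and
#'   `spec`.
#' @export
simulate_experiment <- function(spec, design = NULL, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- seed %||% spec$seed
  seeds <- derive_seeds(seed, 5L + spec$n_runs)
  n_stim <- spec$n_stimuli_train + spec$n_stimuli_test
  design <- design %||% make_event_design(
    n_stim, spec$n_runs, spec$tr_seconds, spec$isi_jitter, seed = seeds[1])

  X <- with_seed(seeds[2],
    matrix(stats::rnorm(n_stim * spec$n_features), n_stim, spec$n_features))
  P <- gen_prf(spec$n_features, seed = seeds[3], n_voxels = spec$n_voxels)
  beta <- X %*% P
  # unit-variance noiseless time series per voxel
  sc <- 1 / col_sd(design$Phi %*% beta)
  beta <- sweep(beta, 2L, sc, "*")
  P <- sweep(P, 2L, sc, "*")

  truth <- list(beta_true = beta, prf_true = P, feature_matrix = X,
                train = seq_len(spec$n_stimuli_train),
                test = spec$n_stimuli_train + seq_len(spec$n_stimuli_test))

  blocks <- run_blocks(design$run_index)
  if (spec$scenario == "ar1_run_effects") {
    vc <- col_var(beta)  # per-voxel common-response variance across stimuli
    cal <- gen_run_effects(n_stim, spec$n_runs, spec$target_split_half,
                           seed = seeds[4], common_variance = 1)
    beta_by_run <- array(NA_real_, c(n_stim, spec$n_voxels, spec$n_runs))
    signal <- matrix(0, nrow(design$Phi), spec$n_voxels)
    for (r in seq_len(spec$n_runs)) {
      dev <- with_seed(seeds[5L + r], matrix(
        stats::rnorm(n_stim * spec$n_voxels), n_stim, spec$n_voxels))
      dev <- sweep(dev, 2L, sqrt(cal$run_variance * vc), "*")
      beta_by_run[, , r] <- beta + dev
      signal[blocks[[r]], ] <- design$Phi[blocks[[r]], , drop = FALSE] %*%
        beta_by_run[, , r]
    }
    truth$beta_by_run <- beta_by_run
    truth$run_effects <- cal[c("run_variance", "proportion", "calibration")]
  } else {
    signal <- design$Phi %*% beta
  }

  noise <- gen_noise(spec, design$run_index, signal_variance = 1,
                     n_voxels = spec$n_voxels, seed = seeds[5])
  data <- ts_dataset(signal + noise, design$run_index, spec$tr_seconds)
  list(data = data, design = design,
       truth = c(truth, list(noise_attr = attributes(noise)[c("scaled_volumes", "factors")])),
       spec = spec)
}
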