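#' @title Single-stimulus response estimation
#' @description Estimate per-stimulus response amplitudes (beta) and their
#'   estimation variance from fMRI time series under different noise models,
#'   following the two-level encoding framework: a GLM at the time-series
#'   level yields responses whose variance feeds the noise ceiling.
#' @name response_estimation
NULL

# ---- response estimate container ---------------------------------------

new_response_estimate <- function(beta_hat, var_diag, sigma2, estimator_kind,
                                  variance_source, n_runs, edf = NA_real_,
                                  beta_by_run = NULL) {
  beta_hat <- as.matrix(beta_hat)
  var_diag <- as.matrix(var_diag)
  stopifnot(dim(beta_hat) == dim(var_diag))
  if (any(var_diag < -1e-10, na.rm = TRUE)) stop("negative estimation variances")
  var_diag[which(var_diag < 0)] <- 0
  structure(list(
    beta_hat = beta_hat,
    var_diag = var_diag,
    beta_by_run = beta_by_run,      # stimuli x voxels x runs
    sigma2 = sigma2,                # per-voxel residual variance scale
    beta_bar = colMeans(beta_hat),
    beta_var = col_var(beta_hat),
    estimator_kind = estimator_kind,
    variance_source = variance_source,
    n_runs = n_runs,
    edf = edf
  ), class = "response_estimate")
}

#' @export
print.response_estimate <- function(x, ...) {
  cat(sprintf("Response estimate [%s]: %d stimuli x %d voxel(s), %d run(s)%s\n",
              x$estimator_kind, nrow(x$beta_hat), ncol(x$beta_hat), x$n_runs,
              if (!is.null(x$beta_by_run)) ", per-run estimates present" else ""))
  invisible(x)
}

check_design_rank <- function(Phi) {
  qr_phi <- qr(Phi)
  p <- ncol(Phi)
  if (qr_phi$rank < p) {
    dep <- qr_phi$pivot[(qr_phi$rank + 1L):p]
    stop(sprintf("design matrix is rank deficient (rank %d < %d); dependent columns: %s",
                 qr_phi$rank, p, paste(dep, collapse = ", ")))
  }
  qr_phi
}

# ---- noise covariance models -------------------------------------------

new_noise_model <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "noise_model")
}

#' Identity (i.i.d.) noise covariance model
#'
#' The noise covariance is the identity exactly; generalized least squares
#' under this model reproduces ordinary least squares.
#' @return A `"noise_model"` object of kind `"identity"`.
#' @export
noise_identity <- function() new_noise_model("identity", pooled = FALSE)

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Noise covariance model: %s\n", x$kind))
  if (x$kind == "ar1")
    cat(sprintf("  mixture weights (identity, AR basis %.2g): %.4g, %.4g; implied lag-1 = %.3f\n",
                x$ar_basis, x$lambda[1], x$lambda[2], implied_lag1(x)))
  if (x$kind == "nonstationary")
    cat(sprintf("  per-volume weights: %d volumes, spread sd/mean = %.3f\n",
                length(x$weights), stats::sd(x$weights) / mean(x$weights)))
  invisible(x)
}

#' Reconstruct the estimated noise covariance of one run
#'
#' @param model A `"noise_model"` object.
#' @param run Run number.
#' @param n_timepoints Run length in volumes (identity/ar1 kinds).
#' @return The run's covariance matrix (up to the per-voxel variance scale).
#' @export
noise_cov_matrix <- function(model, run = 1L, n_timepoints = NULL) {
  switch(model$kind,
    identity = diag(n_timepoints),
    ar1 = {
      Tn <- n_timepoints %||% model$run_lengths[run]
      model$lambda[1] * diag(Tn) + model$lambda[2] * ar_basis_matrix(Tn, model$ar_basis)
    },
    nonstationary = diag(model$weights[model$run_index == unique(model$run_index)[run]]),
    stop("unknown noise model kind"))
}

# off-diagonal AR covariance basis (unit diagonal removed), SPM convention.
# Entries below 1e-8 (lag ~ log(1e-8)/log(a)) are zeroed: they are
# negligible relative to any attainable hyperparameter precision, and
# letting them decay into subnormal floats makes dense algebra drastically
# slower.
ar_basis_matrix <- function(n, a) {
  m <- a^abs(outer(seq_len(n), seq_len(n), "-"))
  m[m < 1e-8] <- 0
  diag(m) <- 0
  m
}

# flush subnormal-range entries produced by exponentially decaying fill-in
flush_tiny <- function(x, tol = 1e-30) {
  x[abs(x) < tol] <- 0
  x
}

#' Implied lag-1 autocorrelation of a fitted AR(1) noise model
#'
#' @param model A `"noise_model"` of kind `"ar1"`.
#' @return The lag-1 autocorrelation of the reconstructed covariance.
#' @export
implied_lag1 <- function(model) {
  stopifnot(model$kind == "ar1")
  model$lambda[2] * model$ar_basis / model$lambda[1]
}

# Pooled second-moment blocks of per-run OLS residuals.  Residuals are
# taken run by run (each run carries one presentation of every stimulus) so
# their covariance is consistent with the per-run restricted projector of
# the REML engines.
pooled_residual_blocks <- function(data, design, voxel_pool = NULL, runs = NULL) {
  pool <- voxel_pool %||% seq_len(ncol(data$signal))
  if (length(pool) < 2L) stop("voxel pool must contain at least 2 voxels")
  blocks <- run_blocks(data$run_index)
  runs <- runs %||% seq_along(blocks)
  lapply(blocks[runs], function(idx) {
    X <- design$Phi[idx, , drop = FALSE]
    Y <- data$signal[idx, pool, drop = FALSE]
    beta <- chol2inv(chol(crossprod(X))) %*% crossprod(X, Y)
    res <- Y - X %*% beta
    tcrossprod(res) / length(pool)
  })
}

#' Estimate an AR(1) noise covariance by pooled REML
#'
#' Two-pass procedure: first-pass OLS residuals from a voxel pool are
#' condensed into per-run second-moment blocks, then the covariance is
#' modelled as a two-component mixture of the identity and a fixed-
#' autocorrelation basis (`ar_basis`, default 0.2), with mixing weights
#' estimated by Fisher-scoring REML.  The same covariance shape is shared by
#' all voxels of the session; per-voxel scale enters through the residual
#' variance at the GLS stage.
#'
#' @param data A [ts_dataset()].
#' @param design A [make_event_design()] design.
#' @param voxel_pool Indices of the voxels pooled for covariance estimation
#'   (default: all voxels; at least 2).
#' @param ar_basis Autocorrelation coefficient of the AR basis component.
#' @param runs Runs used for covariance pooling (default: all).
#' @param max_iter,tol REML iteration cap and relative-change tolerance.
#' @param init Optional starting hyperparameters (e.g. from a previous fit).
#' @param residual_blocks Optional precomputed [pooled_residual_blocks()]
#'   output, shared with other covariance estimators on the same data.
#' @return A `"noise_model"` of kind `"ar1"` with elements `lambda`
#'   (mixture weights), `ar_basis`, `run_lengths`, `reml` (iteration info).
#' @export
estimate_ar1_covariance <- function(data, design, voxel_pool = NULL,
                                    ar_basis = 0.2, runs = NULL,
                                    max_iter = 64, tol = 1e-6, init = NULL,
                                    residual_blocks = NULL) {
  blocks <- run_blocks(data$run_index)
  runs <- runs %||% seq_along(blocks)
  S <- residual_blocks %||% pooled_residual_blocks(data, design, voxel_pool, runs)
  X <- lapply(blocks[runs], function(idx) design$Phi[idx, , drop = FALSE])
  Q <- lapply(blocks[runs], function(idx) {
    Tn <- length(idx)
    list(diag(Tn), ar_basis_matrix(Tn, ar_basis))
  })
  fit <- reml_components(S, X, Q, init = init, max_iter = max_iter, tol = tol)
  new_noise_model("ar1",
    lambda = fit$lambda, ar_basis = ar_basis,
    run_lengths = lengths(blocks), pooled = TRUE,
    pool_size = length(voxel_pool %||% seq_len(ncol(data$signal))),
    reml = fit[c("iterations", "converged")])
}

#' Estimate per-volume noise variances (non-stationary model) by REML
#'
#' Models the noise covariance as diagonal with one variance hyperparameter
#' per acquired volume (RobustWLS convention), estimated from pooled
#' first-pass OLS residuals by Newton-Raphson REML on log-variances.
#' The resulting weights define a weighted least squares fit.
#'
#' @inheritParams estimate_ar1_covariance
#' @param floor_rel Relative floor on the per-volume variances (recorded).
#' @param residual_blocks Optional precomputed [pooled_residual_blocks()]
#'   output, shared with other covariance estimators on the same data.
#' @return A `"noise_model"` of kind `"nonstationary"` with `weights`
#'   (per-volume variances, mean 1), `scale`, `run_index`, `reml`.
#' @export
estimate_nonstationary_weights <- function(data, design, voxel_pool = NULL,
                                           max_iter = 250, tol = 1e-3,
                                           floor_rel = 0.01, init = NULL,
                                           residual_blocks = NULL) {
  blocks <- run_blocks(data$run_index)
  if (any(lengths(blocks) < 2L))
    stop("non-stationary weighting needs at least 2 volumes per run")
  S <- residual_blocks %||% pooled_residual_blocks(data, design, voxel_pool)
  X <- lapply(blocks, function(idx) design$Phi[idx, , drop = FALSE])
  fit <- reml_diag(S, X, init = init, max_iter = max_iter, tol = tol,
                   floor_rel = floor_rel)
  new_noise_model("nonstationary",
    weights = fit$weights, scale = fit$scale, run_index = data$run_index,
    pooled = TRUE, floor = fit$floor,
    pool_size = length(voxel_pool %||% seq_len(ncol(data$signal))),
    reml = fit[c("iterations", "converged")])
}

# ---- GLM fitting --------------------------------------------------------

# whiten (time x k) blocks under a noise model; returns the transformed matrix
whiten <- function(mat, run_index, noise) {
  if (noise$kind == "identity") return(mat)
  if (noise$kind == "nonstationary") return(mat / sqrt(noise$weights))
  blocks <- run_blocks(run_index)
  out <- mat
  # equal-length runs share one Cholesky factor
  lens <- lengths(blocks)
  chols <- new.env()
  for (b in seq_along(blocks)) {
    key <- as.character(lens[b])
    if (is.null(chols[[key]]))
      chols[[key]] <- flush_tiny(chol(noise_cov_matrix(noise, n_timepoints = lens[b])))
    idx <- blocks[[b]]
    out[idx, ] <- backsolve(chols[[key]], mat[idx, , drop = FALSE],
                            transpose = TRUE)
  }
  out
}

#' Fit responses by ordinary least squares
#'
#' Whole-series GLM under i.i.d. noise: `beta = (Phi'Phi)^-1 Phi' y` with
#' per-stimulus estimation variance `sigma2 * diag((Phi'Phi)^-1)`, where
#' `sigma2` is the unbiased residual variance (dof = T - rank).
#'
#' @param data A [ts_dataset()].
#' @param design A `"stim_design"`.
#' @return A list with components `estimate` (a `"response_estimate"`) and
#'   `noise` (the identity `"noise_model"`).
#' @examples
#' d <- make_event_design(8, 2, seed = 1)
#' y <- d$Phi %*% rnorm(8) + rnorm(nrow(d$Phi), sd = 0.5)
#' fit <- fit_ols(ts_dataset(y, d$run_index), d)
#' @export
fit_ols <- function(data, design) {
  fit <- fit_gls(data, design, noise_identity())
  list(estimate = fit, noise = noise_identity())
}

#' Fit responses by generalized least squares
#'
#' `beta = (Phi' W Phi)^-1 Phi' W y` with `W` the inverse of the estimated
#' noise covariance, solved by per-run whitening (never by explicit
#' inversion of the full covariance); the estimation variance is
#' `sigma2 * diag((Phi' W Phi)^-1)` with `sigma2` the whitened residual
#' variance on T - rank degrees of freedom (the trace of the whitened
#' residual-forming matrix).
#'
#' @inheritParams fit_ols
#' @param noise A `"noise_model"` from [noise_identity()],
#'   [estimate_ar1_covariance()] or [estimate_nonstationary_weights()].
#' @return A `"response_estimate"`.
#' @export
fit_gls <- function(data, design, noise = noise_identity()) {
  stopifnot(inherits(data, "ts_dataset"), inherits(design, "stim_design"))
  if (nrow(design$Phi) != nrow(data$signal))
    stop("design and data disagree on the number of time points")
  Xw <- whiten(design$Phi, data$run_index, noise)
  Yw <- whiten(data$signal, data$run_index, noise)
  qr_x <- check_design_rank(Xw)
  beta <- qr.coef(qr_x, Yw)
  res <- qr.resid(qr_x, Yw)
  edf <- nrow(Xw) - qr_x$rank
  sigma2 <- colSums(res^2) / edf
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))[order(qr_x$pivot)]
  var_diag <- outer(xtx_inv_diag, sigma2)
  new_response_estimate(beta, var_diag, sigma2,
                        estimator_kind = noise$kind,
                        variance_source = noise$kind,
                        n_runs = data$n_runs, edf = edf)
}

#' Fit responses run by run
#'
#' Fits the GLM separately within every run (each run contains one
#' presentation of every stimulus) and combines the per-run estimates by
#' averaging.  The per-run estimates feed the run-to-run variance and the
#' split-half procedures.
#'
#' @inheritParams fit_gls
#' @return A `"response_estimate"` with `beta_by_run` filled
#'   (stimuli x voxels x runs), `beta_hat` the across-run mean, and
#'   `var_diag` the parametric per-run variance of the mean.
#' @export
fit_runwise <- function(data, design, noise = noise_identity()) {
  blocks <- run_blocks(data$run_index)
  nr <- length(blocks)
  n <- design$n_stimuli
  V <- ncol(data$signal)
  beta_by_run <- array(NA_real_, c(n, V, nr))
  var_sum <- matrix(0, n, V)
  sig2 <- numeric(V)
  for (r in seq_len(nr)) {
    idx <- blocks[[r]]
    sub <- ts_dataset(data$signal[idx, , drop = FALSE],
                      data$run_index[idx], data$tr_seconds)
    sub_design <- design
    sub_design$Phi <- design$Phi[idx, , drop = FALSE]
    sub_design$run_index <- data$run_index[idx]
    sub_noise <- noise
    if (noise$kind == "nonstationary") {
      sub_noise$weights <- noise$weights[idx]
      sub_noise$run_index <- noise$run_index[idx]
    }
    f <- fit_gls(sub, sub_design, sub_noise)
    beta_by_run[, , r] <- f$beta_hat
    var_sum <- var_sum + f$var_diag
    sig2 <- sig2 + f$sigma2 / nr
  }
  beta_hat <- apply(beta_by_run, c(1, 2), mean)
  new_response_estimate(beta_hat, var_sum / nr^2, sig2,
                        estimator_kind = paste0(noise$kind, "_runwise"),
                        variance_source = noise$kind,
                        n_runs = nr, beta_by_run = beta_by_run)
}

#' Run-to-run variance of the across-run mean response
#'
#' Non-parametric estimation variance per stimulus: the empirical variance
#' of the per-run estimates divided by the number of runs,
#' `sum_r (beta_ir - mean_r)^2 / ((n_r - 1) n_r)`.  Makes no assumption on
#' the noise covariance and absorbs genuine run-to-run response variability.
#'
#' @param est A `"response_estimate"` with per-run estimates present.
#' @return A `"response_estimate"` whose `var_diag` holds the run-to-run
#'   variances and whose `estimator_kind` is `"r2r"`; `beta_hat` is the
#'   across-run mean.
#' @export
run_to_run_variance <- function(est) {
  stopifnot(inherits(est, "response_estimate"))
  if (is.null(est$beta_by_run))
    stop("per-run estimates are required (fit with fit_runwise)")
  nr <- dim(est$beta_by_run)[3]
  if (nr < 2L) stop("run-to-run variance needs at least 2 runs")
  if (anyNA(est$beta_by_run))
    stop("some stimuli are missing from some runs; no imputation is performed")
  m <- apply(est$beta_by_run, c(1, 2), mean)
  ss <- 0
  for (r in seq_len(nr)) ss <- ss + (est$beta_by_run[, , r] - m)^2
  new_response_estimate(m, ss / ((nr - 1) * nr), est$sigma2,
                        estimator_kind = "r2r", variance_source = "r2r",
                        n_runs = nr, beta_by_run = est$beta_by_run)
}
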