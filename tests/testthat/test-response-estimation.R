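# independent oracle for the AR-mixture REML: numerically maximize the
# restricted log-likelihood with generic dense algebra + optim, no Fisher
# scoring, no shared code with the package's iterative engine
reml_oracle <- function(S, X, Q) {
  crit <- function(lam) {
    val <- 0
    for (r in seq_along(S)) {
      Sg <- lam[1] * Q[[r]][[1]] + lam[2] * Q[[r]][[2]]
      ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) return(1e10)
      iSg <- solve(Sg)
      XtX <- t(X[[r]]) %*% iSg %*% X[[r]]
      P <- iSg - iSg %*% X[[r]] %*% solve(XtX, t(X[[r]]) %*% iSg)
      val <- val + sum(log(ev)) + determinant(XtX)$modulus + sum(P * S[[r]])
    }
    val / 2
  }
  stats::optim(c(1, 0.5), crit, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))$par
}

test_that("ordinary least squares matches the hand-computed toy GLM", {
  # single constant regressor over y = (1,2,3): beta = 2, sigma2 = 1, var = 1/3
  fit <- fit_ols(ts_dataset(matrix(c(1, 2, 3)), rep(1L, 3), 1),
                 const_design(3))
  expect_equal(drop(fit$estimate$beta_hat), 2)
  expect_equal(unname(fit$estimate$sigma2), 1)
  expect_equal(drop(fit$estimate$var_diag), 1 / 3)
  expect_equal(fit$noise$kind, "identity")
})

test_that("noiseless data with orthonormal regressors are recovered exactly", {
  set.seed(1)
  Phi <- qr.Q(qr(matrix(stats::rnorm(200 * 5), 200, 5)))
  beta <- stats::rnorm(5)
  d <- structure(list(Phi = Phi, run_index = rep(1L, 200), n_stimuli = 5L,
                      n_runs = 1L, tr_seconds = 1), class = "stim_design")
  fit <- fit_gls(ts_dataset(Phi %*% beta, rep(1L, 200), 1), d)
  expect_equal(drop(fit$beta_hat), beta, tolerance = 1e-10)
  expect_lt(max(fit$var_diag), 1e-20)
})

test_that("rank-deficient designs raise an error naming dependent columns", {
  d <- structure(list(Phi = cbind(1, 1, stats::rnorm(10)), run_index = rep(1L, 10),
                      n_stimuli = 3L, n_runs = 1L, tr_seconds = 1),
                 class = "stim_design")
  expect_error(fit_gls(ts_dataset(matrix(stats::rnorm(10)), rep(1L, 10), 1), d),
               "rank deficient.*columns", perl = TRUE)
})

test_that("OLS estimation variance is calibrated on simulated data", {
  sim <- fx_iid()
  fit <- fit_ols(sim$data, sim$design)
  z <- (fit$estimate$beta_hat - sim$truth$beta_true) /
    sqrt(fit$estimate$var_diag)
  expect_lt(abs(stats::var(as.vector(z)) - 1), 0.1)
})

test_that("GLS with identity covariance reproduces OLS to machine precision", {
  sim <- fx_iid()
  sub <- ts_dataset(sim$data$signal[, 1:3], sim$data$run_index)
  a <- fit_gls(sub, sim$design, noise_identity())
  b <- fit_ols(sub, sim$design)$estimate
  expect_equal(a$beta_hat, b$beta_hat, tolerance = 1e-10)
  expect_equal(a$var_diag, b$var_diag, tolerance = 1e-10)
})

test_that("GLS with a diagonal covariance equals the hand-computed weighted mean", {
  nm <- noiseceiling:::new_noise_model("nonstationary",
                                       weights = c(1, 1, 4, 4),
                                       run_index = rep(1L, 4))
  fit <- fit_gls(ts_dataset(matrix(c(0, 2, 4, 6)), rep(1L, 4), 1),
                 const_design(4), nm)
  expect_equal(drop(fit$beta_hat), 1.8, tolerance = 1e-12)
})

test_that("pooled REML on white noise finds no autocorrelation", {
  sim <- fx_iid()
  m <- estimate_ar1_covariance(sim$data, sim$design)
  expect_lt(abs(implied_lag1(m)), 0.03)
})

test_that("AR-mixture REML reaches the restricted-likelihood optimum", {
  sim <- fx_ar()
  m <- sim$ar_model
  # oracle on a reduced problem (2 runs) to keep optim affordable
  blocks <- noiseceiling:::run_blocks(sim$data$run_index)[1:2]
  S <- sim$S_blocks[1:2]
  X <- lapply(blocks, function(i) sim$design$Phi[i, , drop = FALSE])
  Q <- lapply(blocks, function(i)
    list(diag(length(i)), noiseceiling:::ar_basis_matrix(length(i), 0.2)))
  lam_oracle <- reml_oracle(S, X, Q)
  fit2 <- noiseceiling:::reml_components(S, X, Q)
  expect_equal(fit2$lambda, lam_oracle, tolerance = 5e-3)
  # the fixed-0.2 basis cannot represent AR(0.4) exactly: the optimum sits
  # below the generating lag-1 value; the full fit agrees with the oracle
  lag_oracle <- lam_oracle[2] * 0.2 / lam_oracle[1]
  expect_lt(abs(implied_lag1(m) - lag_oracle), 0.05)
  expect_gt(implied_lag1(m), 0.2)
  expect_lt(implied_lag1(m), 0.4)
})

test_that("reconstructed AR covariance is symmetric positive definite", {
  sim <- fx_ar()
  om <- noise_cov_matrix(sim$ar_model, n_timepoints = 50)
  expect_equal(om, t(om))
  expect_gt(min(eigen(om, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("GLS under the fitted AR model is more efficient than OLS", {
  sim <- fx_ar()
  ols <- fit_ols(sim$data, sim$design)$estimate
  gls <- fit_gls(sim$data, sim$design, sim$ar_model)
  # Gauss-Markov: realized estimation error is smaller under whitening
  mse_ols <- mean((ols$beta_hat - sim$truth$beta_true)^2)
  mse_gls <- mean((gls$beta_hat - sim$truth$beta_true)^2)
  expect_lt(mse_gls, mse_ols)
  # the identity-covariance parametric variance underestimates the realized
  # error (the mechanism behind ceiling overestimation), the AR model's not
  expect_lt(mean(ols$var_diag) / mse_ols, 0.75)
  expect_gt(mean(gls$var_diag) / mse_gls, 0.85)
})

test_that("REML hyperparameters scale with the square of the data scale", {
  sim <- fx_iid()
  sub <- ts_dataset(sim$data$signal[, 1:200], sim$data$run_index)
  m1 <- estimate_ar1_covariance(sub, sim$design)
  sub3 <- ts_dataset(sim$data$signal[, 1:200] * 3, sim$data$run_index)
  m3 <- estimate_ar1_covariance(sub3, sim$design)
  expect_equal(m3$lambda, 9 * m1$lambda, tolerance = 1e-4)
})

test_that("per-volume weights are uniform on stationary white noise", {
  spec <- scenario_spec("iid", snr = 1, n_voxels = 2000, n_replications = 1,
                        seed = 104)
  sim <- simulate_experiment(spec)
  m <- estimate_nonstationary_weights(sim$data, sim$design)
  expect_lt(stats::sd(m$weights) / mean(m$weights), 0.10)
})

test_that("scaled volumes receive the largest estimated variances", {
  sim <- fx_nst()
  m <- sim$nst_model
  scaled <- sim$truth$noise_attr$scaled_volumes
  top <- order(m$weights, decreasing = TRUE)[seq_len(floor(0.1 * length(m$weights)))]
  expect_gte(mean(scaled %in% top), 0.9)
})

test_that("single-volume runs are rejected by the non-stationary model", {
  d <- structure(list(Phi = matrix(1, 3, 1), run_index = c(1L, 1L, 2L),
                      n_stimuli = 1L, n_runs = 2L, tr_seconds = 1),
                 class = "stim_design")
  expect_error(
    estimate_nonstationary_weights(
      ts_dataset(matrix(stats::rnorm(6), 3, 2), c(1L, 1L, 2L), 1), d),
    "at least 2 volumes")
})

test_that("run-to-run variance matches its defining formula", {
  # identical estimates across runs: zero variance
  b <- matrix(stats::rnorm(8), 4, 2)
  est <- make_estimate(b, matrix(0, 4, 2),
                       beta_by_run = array(b, c(4, 2, 3)), n_runs = 3L)
  expect_equal(run_to_run_variance(est)$var_diag, matrix(0, 4, 2))
  # two runs with values {0, 2}: ((0-1)^2 + (2-1)^2) / ((2-1) * 2) = 1
  arr <- array(c(0, 2), c(1, 1, 2))
  est2 <- make_estimate(matrix(1), matrix(0),
                        beta_by_run = arr, n_runs = 2L)
  r <- run_to_run_variance(est2)
  expect_equal(drop(r$var_diag), 1)
  expect_equal(drop(r$beta_hat), 1)
  expect_equal(r$estimator_kind, "r2r")
  # fewer than 2 runs, or missing estimates, are errors
  est1 <- make_estimate(matrix(1), matrix(0),
                        beta_by_run = array(1, c(1, 1, 1)), n_runs = 1L)
  expect_error(run_to_run_variance(est1), "at least 2 runs")
  arr_na <- array(c(0, NA), c(1, 1, 2))
  est_na <- make_estimate(matrix(0), matrix(0), beta_by_run = arr_na,
                          n_runs = 2L)
  expect_error(run_to_run_variance(est_na), "missing")
})

test_that("run-to-run and parametric variances estimate the same quantity", {
  sim <- fx_iid()
  sub <- ts_dataset(sim$data$signal[, 1:100], sim$data$run_index)
  runwise <- fit_runwise(sub, sim$design)
  r2r <- run_to_run_variance(runwise)
  ols <- fit_ols(sub, sim$design)$estimate
  expect_lt(abs(mean(r2r$var_diag) / mean(ols$var_diag) - 1), 0.15)
  # balanced noiseless case: run-averaging equals the whole-series fit
  noiseless <- ts_dataset(sim$design$Phi %*% sim$truth$beta_true[, 1:5],
                          sim$data$run_index)
  rw <- fit_runwise(noiseless, sim$design)
  whole <- fit_ols(noiseless, sim$design)$estimate
  expect_equal(rw$beta_hat, whole$beta_hat, tolerance = 1e-8)
})
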