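test_that("receptive-field draws are reproducible standard normals", {
  expect_identical(gen_prf(128, seed = 4, n_voxels = 3),
                   gen_prf(128, seed = 4, n_voxels = 3))
  draws <- gen_prf(128, seed = 5, n_voxels = 100)
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(stats::var(as.vector(draws)) - 1), 0.05)
  expect_error(gen_prf(0), "at least 1")
})

test_that("AR(1) noise reproduces the requested lag-1 autocorrelation", {
  spec <- scenario_spec("ar1", snr = 1, ar_coefficient = 0.25, n_voxels = 1,
                        n_replications = 1, seed = 1)
  x <- gen_noise(spec, rep(1L, 1e5), signal_variance = 1, n_voxels = 1, seed = 2)
  acf1 <- stats::cor(x[-1, 1], x[-nrow(x), 1])
  expect_lt(abs(acf1 - 0.25), 0.02)
  # realized variance rescaled to the requested SNR
  expect_lt(abs(stats::var(x[, 1]) - 1), 1e-10)
})

test_that("noise is generated independently per run", {
  spec <- scenario_spec("ar1", snr = 1, ar_coefficient = 0.5, n_voxels = 400,
                        n_replications = 1, seed = 1)
  run_index <- rep(1:2, each = 300)
  x <- gen_noise(spec, run_index, 1, n_voxels = 400, seed = 3)
  v <- mean(apply(x, 2, stats::var))
  # lag-1 product within a run reflects the autocorrelation ...
  within <- mean(x[299, ] * x[300, ]) / v
  # ... but vanishes across the run boundary
  across <- mean(x[300, ] * x[301, ]) / v
  expect_gt(within, 0.3)
  expect_lt(abs(across), 0.12)
})

test_that("degenerate noise settings reduce to the i.i.d. generator", {
  spec0 <- scenario_spec("ar1", snr = 2, ar_coefficient = 0, n_voxels = 5,
                         n_replications = 1, seed = 1)
  x <- gen_noise(spec0, rep(1L, 2e4), 1, n_voxels = 5, seed = 4)
  expect_lt(abs(mean(apply(x, 2, stats::var)) - 0.5), 0.02)
  expect_lt(abs(stats::cor(x[-1, 1], x[-2e4, 1])), 0.03)
  spec1 <- scenario_spec("nonstationary", snr = 1, nst_factor = 1,
                         n_voxels = 5, n_replications = 1, seed = 1)
  y <- gen_noise(spec1, rep(1L, 2e4), 1, n_voxels = 5, seed = 4)
  expect_true(all(attr(y, "factors") == 1))
  expect_lt(abs(mean(apply(y, 2, stats::var)) - 1), 0.05)
})

test_that("scenario validation enforces stationarity and parameter ranges", {
  expect_error(scenario_spec("ar1", ar_coefficient = 1.2), "stationary")
  expect_error(scenario_spec("iid", snr = 0), "positive")
  expect_error(scenario_spec("nonstationary", nst_factor = 0.5), "nst_factor")
  expect_error(scenario_spec("ar1_run_effects", target_split_half = 1),
               "strictly between")
})

test_that("run-effect calibration hits the split-half target", {
  expect_error(gen_run_effects(10, 6, 1), "strictly between")
  # balanced halves: closed form, V_r = n_h (1 - t) / t for unit common variance
  cal <- gen_run_effects(168, 6, 0.6, seed = 1)
  expect_equal(cal$run_variance, 3 * 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(cal$proportion, 1 / 3, tolerance = 1e-12)
  expect_equal(cal$calibration, "analytic")
  # odd runs: root search reaches the same target
  cal5 <- gen_run_effects(168, 5, 0.6, seed = 1)
  expect_equal(cal5$calibration, "search")
  f <- 1 / sqrt((1 + cal5$run_variance / 3) * (1 + cal5$run_variance / 2))
  expect_equal(f, 0.6, tolerance = 1e-6)
  # zero run-specific variance: the noiseless halves correlate perfectly
  common <- rnorm(168)
  expect_equal(stats::cor(common, common), 1)

  # Monte Carlo check of the calibration at the response level
  set.seed(42)
  cors <- replicate(200, {
    c0 <- stats::rnorm(168)
    dev <- matrix(stats::rnorm(168 * 6, sd = sqrt(cal$run_variance)), 168, 6)
    b <- c0 + dev
    stats::cor(rowMeans(b[, 1:3]), rowMeans(b[, 4:6]))
  })
  expect_lt(abs(mean(cors) - 0.6), 0.05)
})

test_that("true noise ceiling behaves as the attenuation formula predicts", {
  b <- stats::rnorm(100)
  expect_equal(true_noise_ceiling(b, b), 1)
  expect_equal(true_noise_ceiling(b, -b), -1)
  set.seed(9)
  bt <- stats::rnorm(1e4)
  expect_lt(abs(true_noise_ceiling(bt, bt + stats::rnorm(1e4)) - 1 / sqrt(2)),
            0.02)
  expect_warning(true_noise_ceiling(rep(1, 5), stats::rnorm(5)), "zero variance")
})

test_that("simulated experiments are bit-identical given the same spec", {
  spec <- scenario_spec("ar1_run_effects", snr = 1, n_voxels = 4,
                        n_replications = 1, seed = 77)
  s1 <- simulate_experiment(spec)
  s2 <- simulate_experiment(spec)
  expect_identical(s1$data$signal, s2$data$signal)
  expect_identical(s1$truth$beta_by_run, s2$truth$beta_by_run)
  # noiseless signal has unit variance per voxel (SNR definition)
  spec_iid <- scenario_spec("iid", snr = 4, n_voxels = 10, n_replications = 1,
                            seed = 78)
  sim <- simulate_experiment(spec_iid)
  noiseless <- sim$design$Phi %*% sim$truth$beta_true
  expect_equal(unname(apply(noiseless, 2, stats::var)), rep(1, 10),
               tolerance = 1e-10)
})

test_that("scenario harness is deterministic and handles one replication", {
  spec <- scenario_spec("iid", snr = 1, n_voxels = 20, n_replications = 1,
                        seed = 5)
  r1 <- run_scenario(spec, estimators = c("ols", "r2r", "sh"))
  r2 <- run_scenario(spec, estimators = c("ols", "r2r", "sh"))
  expect_identical(r1$table, r2$table)
  # single replication: percentiles collapse onto the value
  expect_equal(r1$summary$p5, r1$summary$mean, tolerance = 1e-12)
  expect_equal(r1$summary$p95, r1$summary$mean, tolerance = 1e-12)
})

test_that("at very high SNR every estimator approaches a ceiling of one", {
  spec <- scenario_spec("iid", snr = 100, n_voxels = 100, n_replications = 2,
                        seed = 6)
  res <- run_scenario(spec)
  expect_true(all(res$summary$mean >= 0.95))
  expect_true(all(res$summary$true_mean >= 0.95))
})
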