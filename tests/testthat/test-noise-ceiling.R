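test_that("analytical ceiling follows the variance-ratio formula", {
  set.seed(2)
  b <- stats::rnorm(200)
  b <- (b - mean(b)) / stats::sd(b)           # response variance exactly 1
  est <- make_estimate(b, matrix(0.75, 200, 1))
  nc <- analytic_nc(est)
  expect_equal(nc$rho_nc, 0.5, tolerance = 1e-12)
  expect_equal(nc$r2_nc, 0.25, tolerance = 1e-12)
  expect_false(any(nc$clipped))
  # noise-free limit
  nc1 <- analytic_nc(make_estimate(b, matrix(0, 200, 1)))
  expect_equal(nc1$rho_nc, 1)
  # noise variance exceeding response variance clips to zero
  nc0 <- analytic_nc(make_estimate(b, matrix(1.5, 200, 1)))
  expect_equal(nc0$rho_nc, 0)
  expect_true(all(nc0$clipped))
  expect_equal(nc0$r2_nc, 0)
})

test_that("analytical ceiling is strictly decreasing in the noise variance", {
  set.seed(3)
  b <- stats::rnorm(150)
  v <- seq(0, stats::var(b) * 0.99, length.out = 20)
  ncs <- vapply(v, function(vi)
    analytic_nc(make_estimate(b, matrix(vi, 150, 1)))$rho_nc, 0)
  expect_true(all(diff(ncs) < 0))
})

test_that("Monte Carlo ceiling agrees with the analytical value", {
  set.seed(4)
  b <- stats::rnorm(168)
  b <- (b - mean(b)) / stats::sd(b)
  est <- make_estimate(b, matrix(0.75, 168, 1))
  mc <- monte_carlo_nc(est, n_samples = 1000, seed = 10)
  expect_lt(abs(mc$rho_nc - 0.5), 0.03)
  # zero noise: every sampled correlation is 1
  mc0 <- monte_carlo_nc(make_estimate(b, matrix(0, 168, 1)), seed = 1)
  expect_equal(mc0$rho_nc, 1)
  # determinism under a fixed seed
  expect_identical(monte_carlo_nc(est, 1000, seed = 7)$rho_nc,
                   monte_carlo_nc(est, 1000, seed = 7)$rho_nc)
  expect_error(monte_carlo_nc(est, n_samples = 50), "at least 100")
})

test_that("run splitting follows the requested rule and stays disjoint", {
  b <- array(stats::rnorm(5 * 2 * 6), c(5, 2, 6))
  est <- make_estimate(apply(b, c(1, 2), mean), matrix(0, 5, 2),
                       beta_by_run = b, n_runs = 6L)
  h <- split_runs(est, "odd_even")
  expect_equal(h[[1]]$runs, c(1L, 3L, 5L))
  expect_equal(h[[2]]$runs, c(2L, 4L, 6L))
  expect_equal(h[[1]]$beta_hat, apply(b[, , c(1, 3, 5)], c(1, 2), mean))
  h2 <- split_runs(est, "first_second")
  expect_equal(h2[[1]]$runs, 1:3)
  expect_equal(h2[[2]]$runs, 4:6)
  expect_error(split_runs(est, "explicit", halves = list(1:3, 3:6)), "disjoint")
  # odd run count: the first half receives the extra run
  b5 <- array(stats::rnorm(5 * 1 * 5), c(5, 1, 5))
  est5 <- make_estimate(apply(b5, c(1, 2), mean), matrix(0, 5, 1),
                        beta_by_run = b5, n_runs = 5L)
  expect_message(h5 <- split_runs(est5, "first_second"), "extra run")
  expect_equal(lengths(list(h5[[1]]$runs, h5[[2]]$runs)), c(3L, 2L))
})

test_that("split-half ceiling applies the prophecy correction", {
  # two half-estimates whose sample correlation is exactly 1/3
  u1 <- c(-1, 0, 1) / sqrt(2)
  u2 <- c(1, -2, 1) / sqrt(6)
  b1 <- u1
  b2 <- u1 / 3 + sqrt(8 / 9) * u2
  e1 <- make_estimate(b1, matrix(NA_real_, 3, 1))
  e2 <- make_estimate(b2, matrix(NA_real_, 3, 1))
  nc <- split_half_nc(e1, e2)
  expect_equal(nc$details$split_half_rho, 1 / 3, tolerance = 1e-12)
  # corrected reliability 2*(1/3)/(4/3) = 0.5; correlation ceiling sqrt(0.5)
  expect_equal(nc$details$reliability, 0.5, tolerance = 1e-12)
  expect_equal(nc$r2_nc, 0.5, tolerance = 1e-12)
  expect_equal(nc$rho_nc, sqrt(0.5), tolerance = 1e-12)
  # identical halves: ceiling 1
  expect_equal(split_half_nc(e1, e1)$rho_nc, 1)
  # negative split correlation clips to zero
  e3 <- make_estimate(-b1, matrix(NA_real_, 3, 1))
  nc3 <- split_half_nc(e1, e3)
  expect_equal(nc3$rho_nc, 0)
  expect_true(all(nc3$clipped))
  # mismatched stimulus sets are rejected
  e4 <- make_estimate(stats::rnorm(4), matrix(NA_real_, 4, 1))
  expect_error(split_half_nc(e1, e4), "different stimulus sets")
})

test_that("split-half ceiling is unbiased for the two-measurement design", {
  # two independent noisy measurements of the same signal: the corrected
  # reliability estimates rho_nc^2, so sqrt recovers the ceiling
  set.seed(11)
  n <- 168
  rhos <- replicate(300, {
    sig <- stats::rnorm(n)
    m1 <- sig + stats::rnorm(n, sd = 1)   # half-data: 2x the variance
    m2 <- sig + stats::rnorm(n, sd = 1)
    r <- stats::cor(m1, m2)
    if (r > 0) sqrt(2 * r / (1 + r)) else 0
  })
  # full-data ceiling: sqrt(1 / (1 + 0.5))
  expect_lt(abs(mean(rhos) - sqrt(1 / 1.5)), 0.02)
})

test_that("the R-squared domain ceiling is the squared correlation ceiling", {
  expect_equal(nc_to_r2(1), 1)
  expect_equal(nc_to_r2(0), 0)
  expect_equal(nc_to_r2(0.5), 0.25)
  expect_error(nc_to_r2(1.2))
})

test_that("noise-corrected accuracy divides by the ceiling", {
  expect_equal(noise_corrected_accuracy(0.1, 0.2), 0.5, tolerance = 1e-12)
  expect_equal(noise_corrected_accuracy(0.4, 0.8), 0.5, tolerance = 1e-12)
  expect_equal(noise_corrected_accuracy(0.3, 0.3), 1)
  expect_warning(out <- noise_corrected_accuracy(0.3, 0), "zero")
  expect_true(is.na(out))
})
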