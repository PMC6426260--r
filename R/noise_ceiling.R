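#' @title Test-data noise ceiling estimators
#' @description The noise ceiling is the expected prediction accuracy of the
#'   true generating model on noisy test responses: the square root of the
#'   ratio between the variance of the noise-free responses and the variance
#'   of the estimated (noise-contaminated) responses.  Three estimators are
#'   provided: the analytical plug-in, Monte Carlo resampling, and the
#'   Spearman-Brown corrected split-half correlation.
#' @name noise_ceiling
NULL

new_noise_ceiling <- function(rho_nc, method, variance_source,
                              sigma_beta2 = NA_real_, sigma_eps2 = NA_real_,
                              clipped = rep(FALSE, length(rho_nc)),
                              details = list()) {
  stopifnot(all(rho_nc >= 0 | is.na(rho_nc)), all(rho_nc <= 1 + 1e-12 | is.na(rho_nc)))
  structure(list(
    rho_nc = pmin(rho_nc, 1),
    r2_nc = pmin(rho_nc, 1)^2,
    method = method,
    variance_source = variance_source,
    sigma_beta2 = sigma_beta2,
    sigma_eps2 = sigma_eps2,
    clipped = clipped,
    details = details
  ), class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Noise ceiling [%s, variance: %s]: %d voxel(s)\n",
              x$method, x$variance_source, length(x$rho_nc)))
  if (length(x$rho_nc) <= 6) {
    cat("  rho_NC:", format(round(x$rho_nc, 4)), "\n")
  } else {
    cat(sprintf("  rho_NC: median %.4f [%.4f, %.4f]\n",
                stats::median(x$rho_nc, na.rm = TRUE),
                min(x$rho_nc, na.rm = TRUE), max(x$rho_nc, na.rm = TRUE)))
  }
  if (any(x$clipped, na.rm = TRUE))
    cat(sprintf("  %d voxel(s) clipped to zero (negative variance/correlation)\n",
                sum(x$clipped, na.rm = TRUE)))
  invisible(x)
}

#' Analytical noise ceiling
#'
#' Plug-in estimator: with `s2_hat` the variance of the estimated responses
#' across stimuli and `mean(V_ii)` the average per-stimulus estimation
#' variance, the ceiling in correlation units is
#' `sqrt((s2_hat - mean(V_ii)) / s2_hat)`.  A negative radicand (noise
#' variance exceeding response variance) yields a ceiling of zero with
#' `clipped = TRUE`: the best attainable accuracy is chance level.
#'
#' @param est A `"response_estimate"` (variance source is inherited from its
#'   `estimator_kind`: parametric i.i.d./AR(1)/non-stationary, or `"r2r"`).
#' @return A `"noise_ceiling"` object with per-voxel `rho_nc` and `r2_nc`.
#' @examples
#' # s2_hat = 1, mean estimation variance 0.75 -> ceiling 0.5
#' @export
analytic_nc <- function(est) {
  stopifnot(inherits(est, "response_estimate"))
  if (nrow(est$beta_hat) < 3L) stop("at least 3 stimuli are required")
  s2_hat <- est$beta_var
  eps2 <- colMeans(est$var_diag)
  rad <- s2_hat - eps2
  rho <- sqrt(pmax(rad, 0) / s2_hat)
  rho[s2_hat == 0] <- NA_real_
  if (any(s2_hat == 0)) warning("zero response variance: ceiling undefined for some voxels")
  new_noise_ceiling(rho, "analytic", est$variance_source,
                    sigma_beta2 = pmax(rad, 0), sigma_eps2 = eps2,
                    clipped = rad < 0)
}

#' Monte Carlo noise ceiling
#'
#' Resampling version of the same variance decomposition: noise-free signals
#' are drawn from `N(mean(beta_hat), s2_beta)` with
#' `s2_beta = s2_hat - mean(V_ii)` (clipped at zero), measurement noise
#' `N(0, mean(V_ii))` is added, and the ceiling is the median correlation
#' between the noise-free and noise-contaminated draws.
#'
#' @inheritParams analytic_nc
#' @param n_samples Number of Monte Carlo samples (at least 100).
#' @param seed RNG seed; recorded in the output.
#' @return A `"noise_ceiling"` object.
#' @export
monte_carlo_nc <- function(est, n_samples = 1000, seed = NULL) {
  stopifnot(inherits(est, "response_estimate"))
  n <- nrow(est$beta_hat)
  if (n < 3L) stop("at least 3 stimuli are required")
  if (n_samples < 100) stop("n_samples must be at least 100")
  s2_hat <- est$beta_var
  eps2 <- colMeans(est$var_diag)
  s2_beta <- s2_hat - eps2
  V <- ncol(est$beta_hat)
  rho <- numeric(V)
  clipped <- s2_beta < 0
  with_seed(seed, {
    for (v in seq_len(V)) {
      if (s2_hat[v] == 0) { rho[v] <- NA_real_; next }
      if (clipped[v]) { rho[v] <- 0; next }
      signal <- matrix(stats::rnorm(n * n_samples, mean = est$beta_bar[v],
                                    sd = sqrt(s2_beta[v])), n, n_samples)
      noisy <- signal + matrix(stats::rnorm(n * n_samples, sd = sqrt(eps2[v])),
                               n, n_samples)
      rho[v] <- stats::median(col_cor(signal, noisy))
    }
  })
  rho <- pmin(pmax(rho, 0), 1)
  new_noise_ceiling(rho, "monte_carlo", est$variance_source,
                    sigma_beta2 = pmax(s2_beta, 0), sigma_eps2 = eps2,
                    clipped = clipped,
                    details = list(n_samples = n_samples, seed = seed))
}

#' Split runs of a response estimate into two disjoint halves
#'
#' @param est A `"response_estimate"` with per-run estimates.
#' @param rule `"odd_even"` (runs 1,3,5,... vs 2,4,6,...),
#'   `"first_second"` (first half of the runs vs second half), or
#'   `"explicit"` with `halves` a list of two disjoint run-index vectors.
#'   With an odd number of runs the first half receives the extra run
#'   (reported via a message).
#' @param halves For `rule = "explicit"`: list of two disjoint run subsets.
#' @return List of two `"response_estimate"` halves whose `beta_hat` are the
#'   across-run means of the run subsets (recorded in `$runs`).
#' @export
split_runs <- function(est, rule = c("odd_even", "first_second", "explicit"),
                       halves = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(est, "response_estimate"))
  if (is.null(est$beta_by_run)) stop("per-run estimates are required")
  nr <- dim(est$beta_by_run)[3]
  if (nr < 2L) stop("at least 2 runs are required to split")
  if (rule == "explicit") {
    if (is.null(halves) || length(halves) != 2L)
      stop("explicit rule requires `halves`, a list of two run subsets")
    h1 <- as.integer(halves[[1]]); h2 <- as.integer(halves[[2]])
    if (length(intersect(h1, h2)) > 0L) stop("run halves must be disjoint")
    if (!all(c(h1, h2) %in% seq_len(nr))) stop("run indices out of range")
  } else {
    if (nr %% 2L == 1L)
      message(sprintf("odd number of runs (%d): first half receives the extra run", nr))
    if (rule == "odd_even") {
      h1 <- seq(1L, nr, by = 2L); h2 <- seq(2L, nr, by = 2L)
    } else {
      h1 <- seq_len(ceiling(nr / 2)); h2 <- setdiff(seq_len(nr), seq_len(ceiling(nr / 2)))
    }
  }
  half_est <- function(runs) {
    b <- est$beta_by_run[, , runs, drop = FALSE]
    m <- apply(b, c(1, 2), mean)
    out <- new_response_estimate(
      m, matrix(NA_real_, nrow(m), ncol(m)), est$sigma2,
      estimator_kind = paste0(est$estimator_kind, "_half"),
      variance_source = est$variance_source,
      n_runs = length(runs), beta_by_run = b)
    out$runs <- runs
    out
  }
  list(half_est(h1), half_est(h2))
}

#' Split-half noise ceiling
#'
#' Correlates response estimates from two disjoint halves of the data and
#' applies the Spearman-Brown prophecy correction
#' `rel = 2 rho / (rho + 1)`, which maps the half-data correlation `rho` to
#' the reliability of the full data set -- the expected correlation between
#' two independent full replications.  Since two independent measurements
#' each correlate with the noise-free responses by the ceiling itself,
#' `rel` equals the squared ceiling: the correlation-domain ceiling is
#' `sqrt(rel)` and the R-squared-domain ceiling is `rel`.  Negative
#' split-half correlations are mapped to a ceiling of zero
#' (`clipped = TRUE`): chance level is the best attainable accuracy.
#'
#' @param est_half1,est_half2 `"response_estimate"` objects for the same
#'   stimulus set, e.g. from [split_runs()].
#' @return A `"noise_ceiling"` with `variance_source = "none"` (the
#'   procedure does not estimate response variances); the corrected
#'   reliability `2 rho / (rho + 1)` is `r2_nc` (and is kept in
#'   `details$reliability`), `sqrt` of it is `rho_nc`.
#' @export
split_half_nc <- function(est_half1, est_half2) {
  stopifnot(inherits(est_half1, "response_estimate"),
            inherits(est_half2, "response_estimate"))
  if (!identical(dim(est_half1$beta_hat), dim(est_half2$beta_hat)))
    stop("halves estimate different stimulus sets")
  if (!identical(rownames(est_half1$beta_hat), rownames(est_half2$beta_hat)))
    stop("halves estimate different (or differently ordered) stimuli")
  rho <- col_cor(est_half1$beta_hat, est_half2$beta_hat)
  rel <- ifelse(rho > 0, 2 * rho / (rho + 1), 0)
  new_noise_ceiling(sqrt(rel), "split_half", "none",
                    clipped = rho <= 0,
                    details = list(split_half_rho = rho, reliability = rel,
                                   runs = list(est_half1$runs, est_half2$runs)))
}

#' Transform a correlation-domain ceiling to the R-squared domain
#'
#' For the true model the ratio of predicted-to-observed standard deviations
#' equals the ceiling itself and the mean bias is zero, so substituting into
#' the correlation/R-squared relation gives `r2_nc = rho_nc^2`.
#'
#' @param rho_nc Ceiling value(s) in correlation units, in `[0, 1]`.
#' @return Ceiling value(s) in R-squared units.
#' @export
nc_to_r2 <- function(rho_nc) {
  stopifnot(all(rho_nc >= 0 & rho_nc <= 1, na.rm = TRUE))
  rho_nc^2
}

#' Noise-corrected prediction accuracy
#'
#' Ratio of a model's accuracy to the noise ceiling.  Report it alongside --
#' never instead of -- the raw accuracy and the ceiling: the corrected value
#' hides the effect size and the data quality that produced it.
#'
#' @param rho_model Model prediction accuracy (correlation units).
#' @param nc A `"noise_ceiling"` or a numeric ceiling value.
#' @return `rho_model / rho_nc`; `NA` (with a warning) where the ceiling is 0.
#' @examples
#' noise_corrected_accuracy(0.1, 0.2)  # 0.5
#' noise_corrected_accuracy(0.4, 0.8)  # 0.5
#' @export
noise_corrected_accuracy <- function(rho_model, nc) {
  rho_nc <- if (inherits(nc, "noise_ceiling")) nc$rho_nc else nc
  out <- rho_model / rho_nc
  if (any(rho_nc == 0, na.rm = TRUE)) {
    warning("noise ceiling of zero: corrected accuracy undefined, set to NA")
    out[rho_nc == 0] <- NA_real_
  }
  out
}

#' True noise ceiling of a simulation
#'
#' With the generating responses known, the ceiling of a given estimation
#' procedure is the sample correlation between the estimated and the true
#' responses.  It depends on the estimator that produced `beta_hat`:
#' different noise models yield different estimation variance and hence a
#' different ceiling.
#'
#' @param beta_true True responses (vector, or stimuli x voxels matrix).
#' @param beta_hat Estimated responses of matching dimension.
#' @return Correlation(s) between the estimates and the truth.
#' @export
true_noise_ceiling <- function(beta_true, beta_hat) {
  beta_true <- as.matrix(beta_true); beta_hat <- as.matrix(beta_hat)
  stopifnot(dim(beta_true) == dim(beta_hat), nrow(beta_true) >= 3L)
  v1 <- col_var(beta_true); v2 <- col_var(beta_hat)
  if (any(v1 == 0 | v2 == 0))
    warning("zero variance: true noise ceiling undefined for some voxels")
  out <- col_cor(beta_true, beta_hat)
  out[v1 == 0 | v2 == 0] <- NA_real_
  drop(out)
}
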