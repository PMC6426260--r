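# Scenario harness: runs replications of a simulated experiment, applies
# every configured response estimator and ceiling method, and tabulates the
# estimates next to the matched true ceiling.

subset_stimuli <- function(est, idx) {
  out <- est
  out$beta_hat <- est$beta_hat[idx, , drop = FALSE]
  out$var_diag <- est$var_diag[idx, , drop = FALSE]
  if (!is.null(est$beta_by_run))
    out$beta_by_run <- est$beta_by_run[idx, , , drop = FALSE]
  out$beta_bar <- colMeans(out$beta_hat)
  out$beta_var <- col_var(out$beta_hat)
  out
}

subset_voxels <- function(data, v) {
  ts_dataset(data$signal[, v, drop = FALSE], data$run_index, data$tr_seconds)
}

#' Run a simulation scenario across replications
#'
#' For every replication: simulate the experiment, estimate responses under
#' each configured noise model (identity/OLS, AR(1)-REML, non-stationary
#' weights, per-run OLS for the run-to-run and split-half procedures),
#' compute the requested ceiling methods, and record the matched true
#' ceiling (correlation between that estimator's responses and the true
#' run-common responses).  Covariance pooling uses all simulated voxels;
#' ceilings are reported for `report_voxels`.
#'
#' @param spec A [scenario_spec()].
#' @param estimators Subset of `c("ols", "ar1", "nst", "r2r", "sh")`.
#' @param methods `"analytic"` and/or `"mc"` (the split-half estimator is
#'   its own method).
#' @param design Optional fixed design; generated from the spec otherwise.
#' @param mc_samples Monte Carlo samples for `method = "mc"`.
#' @param report_voxels Voxels whose ceilings are tabulated (default: the
#'   first voxel, matching the convention of reporting one voxel from the
#'   pool).
#' @param ar_basis AR basis coefficient for the AR(1)-REML estimator.
#' @param split_rule Run-splitting rule for the split-half estimator.
#' @param use_stimuli Stimulus subset on which ceilings are computed.
#' @return A `"scenario_result"`: list with `table` (one row per
#'   replication x estimator x method x voxel), `summary` (mean and 5th/95th
#'   percentiles per estimator and method, plus the matched true-ceiling
#'   summary), `spec`, and `failures` (per-replication errors, logged and
#'   counted, never dropped silently).
#' @export
run_scenario <- function(spec,
                         estimators = c("ols", "ar1", "nst", "r2r", "sh"),
                         methods = "analytic",
                         design = NULL,
                         mc_samples = 1000,
                         report_voxels = 1L,
                         ar_basis = 0.2,
                         split_rule = "odd_even",
                         use_stimuli = c("all", "test", "train"),
                         progress = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  use_stimuli <- match.arg(use_stimuli)
  stopifnot(all(methods %in% c("analytic", "mc")))

  design <- design %||% make_event_design(
    spec$n_stimuli_train + spec$n_stimuli_test, spec$n_runs,
    spec$tr_seconds, spec$isi_jitter,
    seed = derive_seeds(spec$seed, 1L))
  qr_phi <- check_design_rank(design$Phi)
  xtx_inv <- chol2inv(qr.R(qr_phi))[order(qr_phi$pivot), order(qr_phi$pivot)]
  xtx_inv_diag <- diag(xtx_inv)
  pinv <- tcrossprod(xtx_inv, design$Phi)   # (Phi'Phi)^-1 Phi'
  edf <- nrow(design$Phi) - qr_phi$rank
  # double arithmetic + modulus keeps derived seeds valid for any 32-bit seed
  rep_seeds <- derive_seeds((spec$seed + 1) %% 2147483647, spec$n_replications)
  mc_seeds <- derive_seeds((spec$seed + 2) %% 2147483647, spec$n_replications)

  stim_idx <- function(truth) switch(use_stimuli,
    all = seq_len(nrow(truth$beta_true)), test = truth$test, train = truth$train)

  rows <- list()
  failures <- list()
  ar_init <- NULL

  for (rep in seq_len(spec$n_replications)) {
    res <- tryCatch({
      sim <- simulate_experiment(spec, design, seed = rep_seeds[rep])
      Y <- sim$data$signal
      beta_ols <- pinv %*% Y
      resid_ols <- Y - design$Phi %*% beta_ols
      idx <- stim_idx(sim$truth)
      bt <- sim$truth$beta_true[idx, report_voxels, drop = FALSE]
      rep_data <- subset_voxels(sim$data, report_voxels)

      ests <- list()
      if ("ols" %in% estimators) {
        sig2 <- colSums(resid_ols[, report_voxels, drop = FALSE]^2) / edf
        ests$ols <- new_response_estimate(
          beta_ols[, report_voxels, drop = FALSE],
          outer(xtx_inv_diag, sig2), sig2,
          estimator_kind = "identity", variance_source = "identity",
          n_runs = spec$n_runs, edf = edf)
      }
      Sblocks <- if (any(c("ar1", "nst") %in% estimators))
        pooled_residual_blocks(sim$data, design)
      if ("ar1" %in% estimators) {
        m <- estimate_ar1_covariance(sim$data, design, ar_basis = ar_basis,
                                     init = ar_init, residual_blocks = Sblocks)
        ar_init <- m$lambda
        ests$ar1 <- fit_gls(rep_data, design, m)
      }
      if ("nst" %in% estimators) {
        m <- estimate_nonstationary_weights(sim$data, design,
                                            residual_blocks = Sblocks)
        ests$nst <- fit_gls(rep_data, design, m)
      }
      runwise <- NULL
      if (any(c("r2r", "sh") %in% estimators))
        runwise <- fit_runwise(rep_data, design, noise_identity())
      if ("r2r" %in% estimators)
        ests$r2r <- run_to_run_variance(runwise)

      out <- list()
      for (nm in names(ests)) {
        e <- subset_stimuli(ests[[nm]], idx)
        tnc <- true_noise_ceiling(bt, e$beta_hat)
        for (meth in methods) {
          nc <- if (meth == "analytic") analytic_nc(e)
                else monte_carlo_nc(e, mc_samples, seed = mc_seeds[rep])
          out[[length(out) + 1L]] <- data.frame(
            replication = rep, estimator = nm, method = nc$method,
            voxel = report_voxels, rho_nc = nc$rho_nc, r2_nc = nc$r2_nc,
            true_nc = tnc, true_r2 = tnc^2, clipped = nc$clipped)
        }
      }
      if ("sh" %in% estimators) {
        halves <- split_runs(runwise, split_rule)
        h1 <- subset_stimuli(halves[[1]], idx)
        h2 <- subset_stimuli(halves[[2]], idx)
        nc <- split_half_nc(h1, h2)
        full <- subset_stimuli(runwise, idx)
        tnc <- true_noise_ceiling(bt, full$beta_hat)
        out[[length(out) + 1L]] <- data.frame(
          replication = rep, estimator = "sh", method = nc$method,
          voxel = report_voxels, rho_nc = nc$rho_nc, r2_nc = nc$r2_nc,
          true_nc = tnc, true_r2 = tnc^2, clipped = nc$clipped)
      }
      do.call(rbind, out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(replication = rep,
                                                message = conditionMessage(res))
      warning(sprintf("replication %d failed: %s", rep, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
    if (progress) message(sprintf("replication %d/%d done", rep, spec$n_replications))
  }

  tab <- do.call(rbind, rows)
  summ <- summarize_scenario(tab)
  structure(list(table = tab, summary = summ, spec = spec,
                 failures = failures, n_failed = length(failures)),
            class = "scenario_result")
}

summarize_scenario <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(NULL)
  agg <- function(x) c(mean = mean(x), p5 = unname(stats::quantile(x, 0.05)),
                       p95 = unname(stats::quantile(x, 0.95)), sd = stats::sd(x))
  keys <- unique(tab[, c("estimator", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$estimator == keys$estimator[i] & tab$method == keys$method[i], ]
    est <- agg(sub$rho_nc); tru <- agg(sub$true_nc)
    data.frame(estimator = keys$estimator[i], method = keys$method[i],
               n = nrow(sub),
               mean = est["mean"], p5 = est["p5"], p95 = est["p95"], sd = est["sd"],
               true_mean = tru["mean"], true_p5 = tru["p5"], true_p95 = tru["p95"],
               row.names = NULL)
  }))
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$spec)
  if (x$n_failed > 0) cat(sprintf("  %d replication(s) failed\n", x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Sample-size and regularization experiment
#'
#' Trains the true generating model by ridge regression on noisy response
#' estimates (`beta_hat = beta + noise`, estimation variance `noise_var`)
#' for a grid of training-set sizes and regularization strengths, scores it
#' on a noisy test set, and compares the achieved correlation with the
#' analytical noise ceiling of the same test data.  Because of the
#' bias-variance trade-off of regularization, the true model does not reach
#' the ceiling even for large training sets.
#'
#' @param n_train Training-set sizes (stimuli).
#' @param lambdas Ridge penalties.
#' @param noise_var Estimation variance of the responses (signal variance
#'   is 1).
#' @param n_features Number of model features.
#' @param n_test Test-set size.
#' @param n_replications Replications.
#' @param seed Master seed.
#' @return Data frame: one row per replication x n_train x lambda with the
#'   model correlation `rho_model`, the analytical ceiling `rho_nc` of the
#'   replication's test set, and the predictive R-squared `r2_model`.
#' @export
regularization_experiment <- function(n_train = 126L * c(1L, 2L, 4L, 6L, 8L, 10L),
                                      lambdas = c(1, 1000),
                                      noise_var = 0.5,
                                      n_features = 128L,
                                      n_test = 42L,
                                      n_replications = 50L,
                                      seed = 1L) {
  seeds <- derive_seeds(seed, n_replications)
  n_max <- max(n_train)
  rows <- vector("list", n_replications)
  for (rep in seq_len(n_replications)) {
    rows[[rep]] <- with_seed(seeds[rep], {
      X <- matrix(stats::rnorm((n_max + n_test) * n_features), ncol = n_features)
      P <- stats::rnorm(n_features)
      P <- P / sqrt(sum(P^2))        # unit response variance across stimuli
      beta <- drop(X %*% P)
      beta_hat <- beta + stats::rnorm(length(beta), sd = sqrt(noise_var))
      te <- n_max + seq_len(n_test)
      s2_test <- stats::var(beta_hat[te])
      rho_nc <- sqrt(max(s2_test - noise_var, 0) / s2_test)
      out <- list()
      for (ntr in n_train) {
        for (lam in lambdas) {
          fit <- fit_ridge(beta_hat[seq_len(ntr)], X[seq_len(ntr), , drop = FALSE], lam)
          pred <- predict(fit, X[te, , drop = FALSE])
          m <- score_predictions(beta_hat[te], pred)
          out[[length(out) + 1L]] <- data.frame(
            replication = rep, n_train = ntr, lambda = lam,
            rho_model = m$rho, r2_model = m$r2, rho_nc = rho_nc)
        }
      }
      do.call(rbind, out)
    })
  }
  do.call(rbind, rows)
}
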