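#' @title Linearized encoding models
#' @description Ridge-regression fitting of population receptive fields and
#'   the prediction metrics used to score encoding models on test data:
#'   correlation, predictive R-squared and squared Euclidean distance.
#' @name encoding
NULL

#' Fit a population receptive field by ridge regression
#'
#' Solves `prf = (X'X + lambda I)^-1 X' beta` with the training responses
#' mean-centered first (voxels that differ only in their mean response have
#' the same receptive field).  The system is solved through the SVD of the
#' feature matrix, which is numerically stable for any `lambda >= 0`.
#'
#' @param beta_hat_train Training responses: vector of length `n`, or an
#'   `n x voxels` matrix.
#' @param features_train `n x f` feature matrix of the computational model.
#' @param lambda Ridge regularization strength, `>= 0`.  With `lambda = 0`
#'   the features must have full column rank.
#' @return An `"encoding_fit"` with `prf_hat` (`f x voxels`), `lambda`, and
#'   `centering` (the removed training means).
#' @examples
#' X <- diag(2)
#' fit_ridge(c(2, -2), X, lambda = 1)$prf_hat  # (1, -1)
#' @export
fit_ridge <- function(beta_hat_train, features_train, lambda) {
  beta_hat_train <- as.matrix(beta_hat_train)
  X <- as.matrix(features_train)
  stopifnot(nrow(X) == nrow(beta_hat_train), length(lambda) == 1L, lambda >= 0)
  centering <- colMeans(beta_hat_train)
  bc <- sweep(beta_hat_train, 2L, centering)
  sv <- svd(X)
  if (lambda == 0 && any(sv$d < max(sv$d) * 1e-10))
    stop("features are (numerically) rank deficient with lambda = 0; use lambda > 0")
  shrink <- sv$d / (sv$d^2 + lambda)
  prf <- sv$v %*% (shrink * crossprod(sv$u, bc))
  structure(list(
    prf_hat = prf,
    lambda = lambda,
    centering = centering,
    n_features = ncol(X),
    n_train = nrow(X)
  ), class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("Encoding fit: %d features, %d training stimuli, lambda = %.4g\n",
              x$n_features, x$n_train, x$lambda))
  invisible(x)
}

#' Predict responses to new stimuli
#'
#' `beta_star = X_star prf`.  Predictions are not re-centered: any bias in
#' their mean enters the R-squared metric through the mean-bias term.
#'
#' @param object An `"encoding_fit"`.
#' @param features_test Test feature matrix (`n_test x f`).
#' @param ... Unused.
#' @return Predicted responses (`n_test x voxels`).
#' @export
predict.encoding_fit <- function(object, features_test, ...) {
  features_test <- as.matrix(features_test)
  if (ncol(features_test) != object$n_features)
    stop(sprintf("feature dimension mismatch: fit has %d features, test data %d",
                 object$n_features, ncol(features_test)))
  features_test %*% object$prf_hat
}

#' Score predictions against estimated test responses
#'
#' Computes, per voxel: the sample correlation `rho` (unbiased `n - 1`
#' variances), the predictive R-squared
#' `1 - sum((beta_hat - beta_star)^2) / sum((beta_hat - mean(beta_hat))^2)`
#' (defined in `(-Inf, 1]` on test data), the squared Euclidean distance
#' `d2`, the ratio `gamma` of predicted-to-observed standard deviations, and
#' the prediction mean `pred_mean_bias`.  Unlike `rho`, R-squared is
#' sensitive to a rescaling of the predictions, which matters under
#' regularization.
#'
#' @param beta_hat_test Estimated test responses (vector or `n x voxels`).
#' @param beta_star Predicted responses of matching dimension.
#' @return A `"prediction_metrics"` list of per-voxel vectors: `rho`, `r2`,
#'   `d2`, `gamma`, `pred_mean_bias`, `sigma2_test`, `n`, `flagged` (voxels
#'   with zero test variance, whose metrics are `NA`).
#' @examples
#' m <- score_predictions(c(1, 2, 3), c(1, 1, 3))
#' m$r2   # 0.5
#' @export
score_predictions <- function(beta_hat_test, beta_star) {
  b <- as.matrix(beta_hat_test); p <- as.matrix(beta_star)
  stopifnot(dim(b) == dim(p))
  n <- nrow(b)
  if (n < 3L) stop("at least 3 test stimuli are required")
  s2 <- col_var(b)
  flagged <- s2 == 0
  if (any(flagged)) warning("zero variance in test responses: metrics flagged NA")
  d2 <- colSums((b - p)^2)
  r2 <- 1 - d2 / ((n - 1) * s2)
  rho <- col_cor(b, p)
  gamma <- sqrt(col_var(p) / s2)
  out <- list(rho = rho, r2 = r2, d2 = d2, gamma = gamma,
              pred_mean_bias = colMeans(p), sigma2_test = s2,
              n = n, flagged = flagged)
  for (f in c("rho", "r2", "d2", "gamma")) out[[f]][flagged] <- NA_real_
  structure(out, class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("Prediction metrics (%d test stimuli, %d voxel(s)):\n",
              x$n, length(x$rho)))
  cat(sprintf("  rho: %s  R2: %s\n",
              paste(format(round(utils::head(x$rho, 4), 4)), collapse = " "),
              paste(format(round(utils::head(x$r2, 4), 4)), collapse = " ")))
  invisible(x)
}

#' Residual of the correlation/R-squared identity
#'
#' When the test responses are centered (`mean(beta_hat_test) = 0`), the
#' metrics satisfy
#' `r2 = 2 rho gamma - gamma^2 - n/(n-1) pred_mean_bias^2 / sigma2_test`
#' exactly.  Returns the absolute residual of that identity as an internal
#' consistency check of a scored prediction.
#'
#' @param metrics A `"prediction_metrics"` object from responses that were
#'   centered before scoring.
#' @return Absolute residual(s), one per voxel.
#' @export
r2_identity_check <- function(metrics) {
  stopifnot(inherits(metrics, "prediction_metrics"))
  with(metrics, abs(
    r2 - (2 * rho * gamma - gamma^2 -
            n / (n - 1) * pred_mean_bias^2 / sigma2_test)))
}
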