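# Restricted maximum likelihood engines for the noise-covariance models.
#
# Both engines operate on pooled second-moment blocks of per-run OLS
# residuals, S_r = R_r R_r' / n_pool, one block per run.  The noise
# covariance is block-diagonal over runs (runs are independent
# acquisitions) with hyperparameters shared across runs, and the fixed
# effects (stimulus regressors) are projected out per run, consistent with
# the per-run residuals:
#   P_r = D - D X_r G_r X_r' D,  D = Sigma^-1,  G_r = (X_r' D X_r)^-1.
# Runs of equal length share Sigma and its Cholesky factor.

# Fisher-scoring REML for Sigma = lambda_1 I + sum_{j>1} lambda_j Q_j with
# shared hyperparameters; Q_blocks[[r]][[1]] must be the identity.
# Returns hyperparameters and iteration info; errors carry the trace.
reml_components <- function(S_blocks, X_blocks, Q_blocks,
                            init = NULL, max_iter = 64, tol = 1e-6) {
  nr <- length(S_blocks)
  k <- length(Q_blocks[[1]])
  lens <- vapply(S_blocks, nrow, 1L)
  groups <- split(seq_len(nr), lens)

  if (is.null(init)) {
    # moment start: match pooled lag-0 (and the first off-diagonal when a
    # second component is present)
    d0 <- mean(unlist(lapply(S_blocks, function(s) mean(diag(s)))))
    init <- c(d0, rep(0, k - 1))
    if (k >= 2) {
      l1 <- mean(unlist(lapply(seq_len(nr), function(r) {
        s <- S_blocks[[r]]; q <- Q_blocks[[r]][[2]]
        i1 <- row(s) == col(s) - 1
        mean(s[i1]) / mean(q[i1])
      })))
      init[2] <- l1
    }
  }
  lambda <- init

  sigma_of <- function(lam, r) {
    s <- lam[1] * Q_blocks[[r]][[1]]
    if (k > 1) for (j in 2:k) s <- s + lam[j] * Q_blocks[[r]][[j]]
    s
  }
  chol_groups <- function(lam) {
    out <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      r1 <- groups[[gi]][1]
      ch <- tryCatch(chol(sigma_of(lam, r1)), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      out[[gi]] <- ch
    }
    out
  }

  # shrink the non-leading components until the start is positive definite
  shrink <- 0
  while (is.null(chol_groups(lambda))) {
    shrink <- shrink + 1
    if (shrink > 30) stop("REML: no positive-definite starting value found")
    lambda[-1] <- lambda[-1] / 2
  }

  trace <- matrix(NA_real_, max_iter, k)
  step <- rep(0, k)
  for (it in seq_len(max_iter)) {
    chs <- NULL
    halve <- 0
    repeat {  # step-halving keeps Sigma positive definite
      chs <- chol_groups(lambda)
      if (!is.null(chs)) break
      halve <- halve + 1
      if (halve > 30 || all(step == 0))
        stop("REML: could not keep the covariance positive definite")
      lambda <- lambda - step / 2^halve
    }

    g <- numeric(k)
    H <- matrix(0, k, k)
    for (gi in seq_along(groups)) {
      runs <- groups[[gi]]
      r1 <- runs[1]
      iS <- flush_tiny(chol2inv(chs[[gi]]))
      Q <- Q_blocks[[r1]]
      # shared traces: tr(D Q_i), tr(D Q_i D Q_j), pooled data term
      U <- vector("list", k)       # D Q_j (U[[1]] = D)
      U[[1]] <- iS
      if (k > 1) for (j in 2:k) U[[j]] <- iS %*% Q[[j]]
      Sbar <- Reduce(`+`, S_blocks[runs])
      Zbar <- (iS %*% Sbar) %*% iS # D Sbar D
      trDQ <- vapply(seq_len(k), function(j) sum(iS * Q[[j]]), 0)
      trZQ <- vapply(seq_len(k), function(j) sum(Zbar * Q[[j]]), 0)
      trUU <- matrix(0, k, k)
      for (i in seq_len(k)) for (j in i:k)
        trUU[i, j] <- trUU[j, i] <- sum(U[[i]] * t(U[[j]]))

      g <- g + 0.5 * (trZQ - length(runs) * trDQ)
      H <- H + 0.5 * length(runs) * trUU

      for (r in runs) {
        X <- X_blocks[[r]]
        A <- iS %*% X
        G <- chol2inv(chol(crossprod(X, A)))
        SA <- S_blocks[[r]] %*% A
        iSSA <- iS %*% SA
        Nr <- crossprod(A, SA)
        QA <- vector("list", k)
        B <- vector("list", k)
        M <- vector("list", k)
        for (j in seq_len(k)) {
          QA[[j]] <- if (j == 1) A else Q[[j]] %*% A
          B[[j]] <- iS %*% QA[[j]]
          M[[j]] <- crossprod(A, QA[[j]])
        }
        GNG <- G %*% Nr %*% G
        for (j in seq_len(k)) {
          Cj <- crossprod(QA[[j]], iSSA)
          g[j] <- g[j] - 0.5 * (-sum(G * t(M[[j]]))) -
            0.5 * (2 * sum(G * t(Cj)) - sum(GNG * t(M[[j]])))
          for (l in seq_len(k)) {
            Cjl <- crossprod(QA[[j]], B[[l]])
            H[j, l] <- H[j, l] + 0.5 *
              (-2 * sum(G * t(Cjl)) + sum((G %*% M[[j]] %*% G) * t(M[[l]])))
          }
        }
      }
    }
    H <- (H + t(H)) / 2

    step <- tryCatch(solve(H, g), error = function(e) g / pmax(diag(H), 1e-12))
    cap <- 10 * pmax(abs(lambda), mean(abs(lambda)))
    step <- pmin(pmax(step, -cap), cap)
    lambda <- lambda + step
    trace[it, ] <- lambda
    rel <- max(abs(step) / pmax(abs(lambda), 1e-12))
    if (rel < tol) {
      return(list(lambda = lambda, iterations = it, converged = TRUE,
                  trace = trace[seq_len(it), , drop = FALSE]))
    }
  }
  cond <- simpleError(sprintf(
    "REML did not converge within %d iterations (last relative change %.2e)",
    max_iter, max(abs(step) / pmax(abs(lambda), 1e-12))))
  cond$trace <- trace
  stop(cond)
}

# Newton-Raphson (diagonal Fisher-scored) REML for a diagonal covariance
# with one variance hyperparameter per volume, log-parametrized for
# positivity (RobustWLS convention).  Returns per-volume variances for the
# whole series, normalized to mean 1, plus the overall scale.
reml_diag <- function(S_blocks, X_blocks, init = NULL,
                      max_iter = 250, tol = 1e-3, floor_rel = 0.01) {
  nr <- length(S_blocks)
  Tr <- vapply(S_blocks, nrow, 1L)
  if (any(Tr < 2L)) stop("non-stationary REML needs at least 2 volumes per run")
  idx <- split(seq_len(sum(Tr)), rep(seq_len(nr), Tr))

  s2 <- if (is.null(init)) {
    # leverage-corrected start: E[diag(S)] = sigma_t^2 (1 - h_tt) under OLS
    unlist(lapply(seq_len(nr), function(r) {
      qx <- qr(X_blocks[[r]])
      h <- rowSums(qr.Q(qx)^2)
      pmax(diag(S_blocks[[r]]) / pmax(1 - h, 0.05), .Machine$double.eps)
    }))
  } else init
  logs <- log(s2)
  # variance floor: under misspecified (e.g. strongly autocorrelated) noise
  # the unconstrained diagonal REML can drive single-volume variances to
  # zero; the floor keeps the weighted fit non-degenerate and is recorded
  flo_log <- log(floor_rel * mean(s2))
  step <- prev_step <- numeric(sum(Tr))
  damp <- rep(1, sum(Tr))  # per-coordinate damping against Jacobi oscillation

  for (it in seq_len(max_iter)) {
    s2 <- exp(logs)
    dP <- dPSP <- numeric(sum(Tr))
    for (r in seq_len(nr)) {
      d <- 1 / s2[idx[[r]]]
      A <- X_blocks[[r]] * d
      G <- chol2inv(chol(crossprod(X_blocks[[r]], A)))
      AG <- A %*% G
      Pr <- -tcrossprod(AG, A)            # - D X G X' D
      diag(Pr) <- diag(Pr) + d
      PS <- d * S_blocks[[r]] - AG %*% crossprod(A, S_blocks[[r]])
      dP[idx[[r]]] <- diag(Pr)
      dPSP[idx[[r]]] <- rowSums(PS * Pr)  # Pr symmetric
    }
    # log-scale Fisher step: g_t = -s2*(P_tt - (PSP)_tt)/2, H_t = s2^2 P_tt^2 / 2
    step <- (dPSP - dP) / (s2 * dP^2)
    flip <- sign(step) * sign(prev_step) < 0
    damp[flip] <- damp[flip] * 0.5
    damp[!flip] <- pmin(1, damp[!flip] * 1.2)
    prev_step <- step
    step <- pmin(pmax(damp * step, -2), 2)
    logs <- logs + step
    at_floor <- logs <= flo_log
    logs[at_floor] <- flo_log
    if (all(at_floor) || max(abs(step[!at_floor])) < tol) {
      s2 <- exp(logs)
      return(list(weights = s2 / mean(s2), scale = mean(s2),
                  iterations = it, converged = TRUE, floor = floor_rel,
                  n_floored = sum(at_floor)))
    }
  }
  cond <- simpleError(sprintf(
    "non-stationary REML did not converge within %d iterations (max |step| %.2e)",
    max_iter, max(abs(step))))
  cond$trace <- logs
  stop(cond)
}
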