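# internal helpers shared across modules

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed leaves the global stream untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Independent sub-seeds derived from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# unbiased column variances / sds of a matrix
col_var <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

col_sd <- function(x) sqrt(pmax(col_var(x), 0))

# column-wise Pearson correlation between paired columns of two matrices
col_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(dim(a) == dim(b))
  n <- nrow(a)
  ma <- colMeans(a); mb <- colMeans(b)
  cov_ab <- (colSums(a * b) - n * ma * mb) / (n - 1)
  cov_ab / sqrt(col_var(a) * col_var(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
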