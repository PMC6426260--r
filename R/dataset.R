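#' Construct an fMRI time-series dataset
#'
#' Bundles a (time points x voxels) BOLD signal matrix with its run
#' structure.  Validation enforces finite entries and contiguous, nonempty
#' run blocks; estimation functions rely on both.
#'
#' @param signal Numeric matrix, time points x voxels.
#' @param run_index Integer vector of per-time-point run labels (contiguous
#'   non-decreasing blocks, every run nonempty).
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `"ts_dataset"`.
#' @examples
#' d <- ts_dataset(matrix(rnorm(20), 10, 2), rep(1:2, each = 5), 2.6)
#' @export
ts_dataset <- function(signal, run_index, tr_seconds = 2.6) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!all(is.finite(signal))) stop("signal contains non-finite entries")
  run_index <- as.integer(run_index)
  if (length(run_index) != nrow(signal))
    stop("length(run_index) must equal nrow(signal)")
  validate_run_index(run_index)
  structure(list(
    signal = signal,
    run_index = run_index,
    n_runs = length(unique(run_index)),
    tr_seconds = tr_seconds
  ), class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("fMRI dataset: %d time points x %d voxel(s), %d run(s), TR = %.3g s\n",
              nrow(x$signal), ncol(x$signal), x$n_runs, x$tr_seconds))
  invisible(x)
}

# list of row-index vectors, one per run, in run order
run_blocks <- function(run_index) {
  split(seq_along(run_index), factor(run_index, levels = unique(run_index)))
}
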