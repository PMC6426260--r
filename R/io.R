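#' @title File input/output
#' @description Readers and writers for the formats the package exchanges:
#'   tab-delimited matrices and event tables, JSON scenario configurations
#'   and provenance sidecars, and (optionally, via RNifti) NIfTI volumes.
#' @name io
NULL

#' Write / read a scenario specification as JSON
#'
#' The JSON round trip is lossless: `read_scenario_spec(write_scenario_spec(s))`
#' reproduces the validated spec.
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `write_scenario_spec` returns `path` invisibly;
#'   `read_scenario_spec` returns a validated `"scenario_spec"`.
#' @export
write_scenario_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_spec
#' @export
read_scenario_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario_spec, x)
}

#' Read / write a dense time-series matrix with a run sidecar
#'
#' The matrix is stored as a tab-delimited table (one row per time point,
#' one column per voxel, single header line), the run structure as a JSON
#' sidecar `{"run_lengths": [...], "tr_seconds": ...}`.
#'
#' @param data A [ts_dataset()].
#' @param path Matrix file path; the sidecar is `<path>.runs.json` unless
#'   given explicitly.
#' @param sidecar Optional sidecar path.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` a `"ts_dataset"`.
#' @export
write_timeseries_tsv <- function(data, path, sidecar = paste0(path, ".runs.json")) {
  stopifnot(inherits(data, "ts_dataset"))
  utils::write.table(data$signal, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("voxel", seq_len(ncol(data$signal))),
                     quote = FALSE)
  jsonlite::write_json(list(run_lengths = as.integer(table(factor(
                         data$run_index, levels = unique(data$run_index)))),
                       tr_seconds = data$tr_seconds),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path, sidecar = paste0(path, ".runs.json")) {
  if (!file.exists(sidecar))
    stop(sprintf("run sidecar not found: expected '%s' next to '%s'", sidecar, path))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.delim(path, check.names = FALSE))
  run_index <- rep(seq_along(side$run_lengths), side$run_lengths)
  ts_dataset(mat, run_index, side$tr_seconds %||% 2.6)
}

#' Read / write an event table
#'
#' Tab-delimited with columns `onset_seconds`, `duration_seconds`,
#' `stimulus_id` and optionally `run`.
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `read_event_table` returns the validated data frame.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- utils::read.delim(path)
  need <- c("onset_seconds", "stimulus_id")
  if (!all(need %in% names(ev)))
    stop(sprintf("event table must contain columns %s", paste(need, collapse = ", ")))
  ev
}

#' Write a result table (tab-delimited, one header line)
#'
#' @param table Data frame.
#' @param path File path.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# provenance sidecar: configuration hash, package version, seed, extras
write_provenance <- function(path, config, seed = NULL, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  prov <- c(list(
    package = "noiseceiling",
    version = as.character(utils::packageVersion("noiseceiling")),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a simulated series as 4D NIfTI / import it back
#'
#' Voxels are laid out along the first spatial axis, time along the fourth.
#' Requires the RNifti package.
#'
#' @param data A [ts_dataset()].
#' @param path `.nii` or `.nii.gz` path; run structure goes to
#'   `<path>.runs.json`.
#' @param sidecar Optional sidecar path.
#' @return The path (write) or a `"ts_dataset"` (read).
#' @export
write_nifti_series <- function(data, path, sidecar = paste0(path, ".runs.json")) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
  stopifnot(inherits(data, "ts_dataset"))
  arr <- array(t(data$signal), dim = c(ncol(data$signal), 1L, 1L, nrow(data$signal)))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, data$tr_seconds))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(run_lengths = as.integer(table(factor(
                         data$run_index, levels = unique(data$run_index)))),
                       tr_seconds = data$tr_seconds),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nifti_series
#' @export
read_nifti_series <- function(path, sidecar = paste0(path, ".runs.json")) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI import requires the RNifti package")
  if (!file.exists(sidecar))
    stop(sprintf("run sidecar not found: expected '%s' next to '%s'", sidecar, path))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  arr <- RNifti::asNifti(RNifti::readNifti(path))
  d <- dim(arr)
  mat <- t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  run_index <- rep(seq_along(side$run_lengths), side$run_lengths)
  ts_dataset(mat, run_index, side$tr_seconds %||% 2.6)
}

#' Read per-run response estimates from a long-format table
#'
#' Tab-delimited with columns `run`, `stimulus`, `voxel`, `beta`: the
#' precomputed-responses entry point that bypasses the GLM stage (only the
#' run-to-run and split-half ceilings are available from it).
#'
#' @param path File path.
#' @return A `"response_estimate"` with `beta_by_run` filled.
#' @export
read_beta_by_run <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("run", "stimulus", "voxel", "beta")
  if (!all(need %in% names(tab)))
    stop(sprintf("per-run response table must contain columns %s",
                 paste(need, collapse = ", ")))
  runs <- sort(unique(tab$run)); stims <- sort(unique(tab$stimulus))
  voxs <- sort(unique(tab$voxel))
  arr <- array(NA_real_, c(length(stims), length(voxs), length(runs)))
  arr[cbind(match(tab$stimulus, stims), match(tab$voxel, voxs),
            match(tab$run, runs))] <- tab$beta
  if (anyNA(arr))
    stop("per-run response table is incomplete: every stimulus must be estimated in every run")
  m <- apply(arr, c(1, 2), mean)
  new_response_estimate(m, matrix(0, nrow(m), ncol(m)), rep(NA_real_, ncol(m)),
                        estimator_kind = "precomputed", variance_source = "none",
                        n_runs = length(runs), beta_by_run = arr)
}
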