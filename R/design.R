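#' Build a fast event-related stimulus design
#'
#' Lays out one presentation of every stimulus per run, in seeded random
#' order, with a jittered inter-stimulus interval drawn uniformly from
#' `isi_jitter` (in TRs), and convolves the per-stimulus event indicator
#' trains with the canonical double-gamma HRF sampled at the TR.  The design
#' is block structured: the HRF never bleeds across run boundaries, so
#' responses estimated per run use disjoint data.
#'
#' @param n_stimuli Number of distinct stimuli (columns of the design).
#' @param n_runs Number of runs; every stimulus appears exactly once per run.
#' @param tr_seconds Repetition time in seconds. Default 2.6.
#' @param isi_jitter Candidate inter-stimulus intervals in TRs. Default 2:4.
#' @param run_length_tr Optional fixed run length in TRs.  When supplied and
#'   too short to place all events plus the HRF tail, an error is raised;
#'   when `NULL` the run length is sized automatically.
#' @param seed Optional RNG seed controlling stimulus order and jitter.
#' @param hrf Optional HRF kernel sampled at the TR; defaults to
#'   [canonical_hrf()] over 32 s.
#' @return An object of class `"stim_design"`: a list with the convolved
#'   design matrix `Phi` (time points x stimuli), the per-time-point
#'   `run_index`, an `events` table (`run`, `stimulus`, `onset_tr`,
#'   `onset_seconds`), `tr_seconds`, `n_runs` and `n_stimuli`.
#' @examples
#' d <- make_event_design(12, 2, seed = 1)
#' dim(d$Phi)
#' @export
make_event_design <- function(n_stimuli, n_runs, tr_seconds = 2.6,
                              isi_jitter = c(2L, 3L, 4L), run_length_tr = NULL,
                              seed = NULL, hrf = NULL) {
  stopifnot(n_stimuli >= 1, n_runs >= 1, tr_seconds > 0)
  isi_jitter <- as.integer(isi_jitter)
  if (any(isi_jitter <= 0)) stop("isi_jitter values must be positive (TRs)")
  hrf <- hrf %||% sampled_hrf(tr_seconds)
  lh <- length(hrf)
  start_tr <- 2L  # volumes before the first event of each run

  events <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      order <- sample.int(n_stimuli)
      gaps <- sample(isi_jitter, n_stimuli, replace = TRUE)
      onset <- start_tr + cumsum(c(0L, gaps[-n_stimuli]))
      data.frame(run = r, stimulus = order, onset_tr = onset)
    }))
  })

  needed <- max(events$onset_tr) + lh  # room for the HRF tail
  if (is.null(run_length_tr)) {
    run_length_tr <- needed
  } else if (run_length_tr < needed) {
    stop(sprintf(
      "run_length_tr = %d is too short to place all events: %d volumes needed (last onset %d TR + %d TR HRF tail)",
      run_length_tr, needed, max(events$onset_tr), lh))
  }

  Phi <- matrix(0, nrow = run_length_tr * n_runs, ncol = n_stimuli)
  for (k in seq_len(nrow(events))) {
    t0 <- (events$run[k] - 1L) * run_length_tr + events$onset_tr[k] + 1L
    run_end <- events$run[k] * run_length_tr
    idx <- t0:min(t0 + lh - 1L, run_end)
    Phi[idx, events$stimulus[k]] <- Phi[idx, events$stimulus[k]] + hrf[seq_along(idx)]
  }
  events$onset_seconds <- events$onset_tr * tr_seconds

  structure(list(
    Phi = Phi,
    run_index = rep(seq_len(n_runs), each = run_length_tr),
    events = events,
    tr_seconds = tr_seconds,
    n_runs = n_runs,
    n_stimuli = n_stimuli,
    run_length_tr = run_length_tr,
    hrf = hrf
  ), class = "stim_design")
}

#' Build a stimulus design from an event table
#'
#' Converts a long-format event table (as read by [read_event_table()]) into
#' a convolved design matrix on the volume grid of an acquired data set.
#' Onsets are assigned to the nearest volume within their run.
#'
#' @param events Data frame with columns `onset_seconds`, `stimulus_id` and
#'   either `run` or a single implicit run.
#' @param run_index Integer vector of per-volume run labels (contiguous,
#'   non-decreasing), one entry per acquired volume.
#' @param tr_seconds Repetition time in seconds.
#' @param hrf Optional HRF kernel sampled at the TR.
#' @return A `"stim_design"` object (see [make_event_design()]).
#' @export
design_from_events <- function(events, run_index, tr_seconds, hrf = NULL) {
  stopifnot(all(c("onset_seconds", "stimulus_id") %in% names(events)))
  run_index <- as.integer(run_index)
  validate_run_index(run_index)
  if (is.null(events$run)) events$run <- 1L
  hrf <- hrf %||% sampled_hrf(tr_seconds)
  lh <- length(hrf)

  stim_ids <- sort(unique(events$stimulus_id))
  n_stimuli <- length(stim_ids)
  Tn <- length(run_index)
  run_start <- c(1L, which(diff(run_index) != 0L) + 1L)
  run_end <- c(run_start[-1L] - 1L, Tn)
  Phi <- matrix(0, Tn, n_stimuli)
  for (k in seq_len(nrow(events))) {
    r <- match(events$run[k], unique(run_index))
    onset_vol <- run_start[r] + as.integer(round(events$onset_seconds[k] / tr_seconds))
    if (onset_vol > run_end[r])
      stop(sprintf("event %d (onset %.1f s) falls beyond the end of run %d",
                   k, events$onset_seconds[k], events$run[k]))
    j <- match(events$stimulus_id[k], stim_ids)
    idx <- onset_vol:min(onset_vol + lh - 1L, run_end[r])
    Phi[idx, j] <- Phi[idx, j] + hrf[seq_along(idx)]
  }
  ev <- data.frame(run = events$run,
                   stimulus = match(events$stimulus_id, stim_ids),
                   onset_tr = as.integer(round(events$onset_seconds / tr_seconds)),
                   onset_seconds = events$onset_seconds)
  structure(list(
    Phi = Phi, run_index = run_index, events = ev, tr_seconds = tr_seconds,
    n_runs = length(unique(run_index)), n_stimuli = n_stimuli,
    run_length_tr = NA_integer_, hrf = hrf, stimulus_ids = stim_ids
  ), class = "stim_design")
}

#' @export
print.stim_design <- function(x, ...) {
  cat(sprintf("Stimulus design: %d time points, %d stimuli, %d run(s), TR = %.3g s\n",
              nrow(x$Phi), x$n_stimuli, x$n_runs, x$tr_seconds))
  invisible(x)
}

validate_run_index <- function(run_index) {
  if (length(run_index) == 0L) stop("run_index is empty")
  if (any(diff(match(run_index, unique(run_index))) < 0))
    stop("run_index must consist of contiguous, non-decreasing run blocks")
  invisible(run_index)
}
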