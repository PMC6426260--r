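#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities in the SPM convention: a response gamma
#' peaking around `peak` seconds minus an undershoot gamma peaking around
#' `undershoot` seconds, scaled by `1/ratio`.  The returned kernel is
#' normalized to a maximum of 1 so that event amplitudes carry the units.
#'
#' @param t Time points in seconds (non-negative) at which to sample the HRF.
#' @param peak Delay (shape, in seconds) of the response gamma. Default 6.
#' @param undershoot Delay of the undershoot gamma. Default 16.
#' @param ratio Peak-to-undershoot amplitude ratio. Default 6.
#' @return Numeric vector, `length(t)` samples of the HRF.
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 2.6))
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(all(t >= 0), peak > 0, undershoot > 0, ratio > 0)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

# HRF sampled on the TR grid, covering `span_seconds` of post-stimulus time
sampled_hrf <- function(tr_seconds, span_seconds = 32) {
  canonical_hrf(seq(0, span_seconds, by = tr_seconds))
}
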