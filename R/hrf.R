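# Canonical double-gamma hemodynamic response function.

#' Double-gamma hemodynamic response function
#'
#' The conventional difference-of-gammas BOLD impulse response: a gamma
#' density peaking near `peakDelay` seconds minus a later undershoot gamma
#' scaled by `1/ratio`, normalized to unit peak amplitude. With the default
#' parameters (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot 6:1) the maximum falls near 5 s after onset and the
#' response has returned to within 1% of baseline by 30 s.
#'
#' @param t Time in seconds from event onset (t >= 0; values below 0 error).
#' @param peakDelay,peakDisp Shape-determining delay and dispersion of the
#'   positive lobe (gamma shape `peakDelay/peakDisp`, scale `peakDisp`).
#' @param undershootDelay,undershootDisp Same for the undershoot lobe.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of response amplitudes, unit peak.
#' @export
hrf <- function(t, peakDelay = 6, undershootDelay = 16,
                peakDisp = 1, undershootDisp = 1, ratio = 6) {
  if (any(t < 0)) stop("t must be >= 0")
  if (peakDelay <= 0 || undershootDelay <= 0 || peakDisp <= 0 ||
      undershootDisp <= 0 || ratio <= 0)
    stop("HRF shape parameters must be positive")
  raw <- function(tt)
    stats::dgamma(tt, shape = peakDelay / peakDisp, scale = peakDisp) -
      stats::dgamma(tt, shape = undershootDelay / undershootDisp,
                    scale = undershootDisp) / ratio
  grid <- seq(0, 32, by = 0.01)
  peak <- max(raw(grid))
  raw(t) / peak
}
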