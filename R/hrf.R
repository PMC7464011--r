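#' Canonical double-gamma hemodynamic response function
#'
#' The conventional two-gamma impulse response used to model the hemodynamic
#' response to a brief neural event: a positive gamma density peaking around
#' 5 s minus a scaled second gamma capturing the post-stimulus undershoot
#' around 15 s. With the default parameters `hrf(0) = 0`, the peak falls near
#' `(peak_shape - 1) / rate` = 5 s, and the function integrates to
#' `1 - 1/undershoot_ratio` > 0.
#'
#' @param t time in seconds (vectorized); must be non-negative.
#' @param peak_shape shape of the positive gamma lobe (default 6).
#' @param undershoot_shape shape of the undershoot lobe (default 16).
#' @param rate common rate parameter in 1/s (default 1).
#' @param undershoot_ratio positive lobe : undershoot amplitude ratio
#'   (default 6, i.e. the undershoot is 1/6 the size).
#' @return numeric vector of response values (arbitrary units).
#' @examples
#' tt <- seq(0, 30, by = 0.1)
#' h <- hrf(tt)
#' tt[which.max(h)] # about 5 s
#' @export
hrf <- function(t, peak_shape = 6, undershoot_shape = 16, rate = 1,
                undershoot_ratio = 6) {
  if (any(t < 0)) stop("`t` must be non-negative")
  stats::dgamma(t, shape = peak_shape, rate = rate) -
    stats::dgamma(t, shape = undershoot_shape, rate = rate) / undershoot_ratio
}

# Convolve the game-block boxcar of `schedule` with the HRF on a grid at `fs`,
# and scale so the plateau response has unit peak. The returned regressor
# multiplied by an amplitude is the noiseless deep-channel neural component.
neural_regressor <- function(schedule, fs, n = NULL, hrf_span_s = NULL) {
  if (is.null(n)) n <- round(schedule_duration(schedule) * fs)
  if (is.null(hrf_span_s)) hrf_span_s <- (n - 1) / fs
  t <- (seq_len(n) - 1) / fs
  boxcar <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    if (schedule$label[i] == "game") {
      boxcar[block_sample_index(schedule, i, fs, n)] <- 1
    }
  }
  kern <- hrf(seq(0, hrf_span_s, by = 1 / fs))
  reg <- stats::convolve(boxcar, rev(kern), type = "open")[seq_len(n)] / fs
  peak <- max(abs(reg))
  if (peak > 0) reg <- reg / peak
  reg
}
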