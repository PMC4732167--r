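#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a double-pass (forward then backward) Butterworth low-pass filter,
#' the standard preprocessing for body-worn inertial signals: the second pass
#' cancels the phase distortion of the first, so gait events keep their timing.
#' The effective amplitude response is the squared magnitude of the single-pass
#' filter. Edges are handled by odd-reflection padding of length
#' `3 * (order + 1)` samples before the double pass.
#'
#' @param x Numeric vector, the signal to filter.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 5 Hz, suited to gait, whose
#'   locomotor power sits below ~4 Hz).
#' @param order Filter order of each pass (default 2).
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 128)
#' x <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 30 * t)
#' y <- lowpass_filter(x, fs = 128)
#' @export
lowpass_filter <- function(x, fs, cutoff = 5, order = 2) {
  x <- as.numeric(x)
  npad <- 3L * (order + 1L)
  if (length(x) <= npad) {
    stop("signal too short for stable double-pass filtering: need length > ",
         npad, ", got ", length(x), call. = FALSE)
  }
  if (!(cutoff > 0) || cutoff >= fs / 2) {
    stop("cutoff must satisfy 0 < cutoff < fs/2 (Nyquist); got cutoff = ",
         cutoff, " at fs = ", fs, call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  n <- length(x)
  # odd (point-symmetric) reflection about the end samples; each pass starts
  # from steady state at its first padded sample so no start-up transient
  # leaks into the signal
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  pass <- function(v) {
    as.numeric(signal::filter(bf, v,
                              init.x = rep(v[1], length(bf$b) - 1L),
                              init.y = rep(v[1], length(bf$a) - 1L)))
  }
  y <- rev(pass(rev(pass(xp))))
  y[(npad + 1L):(npad + n)]
}

# Filter all nine signal columns of a trial in place.
filter_trial <- function(trial, cutoff = 5, order = 2) {
  for (nm in c("shank_acc", "shank_gyro", "waist_acc")) {
    trial[[nm]] <- apply(trial[[nm]], 2, lowpass_filter, fs = trial$fs,
                         cutoff = cutoff, order = order)
  }
  trial
}
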