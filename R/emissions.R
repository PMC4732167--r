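# Observation sequences fed to the gait HMMs: seven channels derived from one
# shank sensor plus the waist ML accelerometer, in a fixed order.

EMISSION_CHANNELS <- c("gyro_ml", "d_gyro_ml", "acc_ap", "d_acc_ap",
                       "d_acc_ml", "d_acc_vt", "waist_acc_ml")

#' Approximate time derivative of a sampled signal
#'
#' Forward first difference scaled by the sampling rate; the last value is
#' repeated so the output keeps the input length.
#'
#' @param x Numeric vector, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector, same length as `x`.
#' @export
approx_derivative <- function(x, fs) {
  if (length(x) < 2L) {
    stop("approx_derivative needs at least 2 samples", call. = FALSE)
  }
  d <- diff(x) * fs
  c(d, d[length(d)])
}

#' Build the 7-channel HMM observation matrix for a trial
#'
#' Columns, in fixed order: shank ML angular velocity and its approximated
#' derivative, shank AP acceleration and its approximated derivative,
#' approximated derivatives of the shank ML and VT accelerations, and the
#' waist ML acceleration. For left-side trials the waist ML column is
#' sign-flipped so the lateral sway has the same polarity for both sides.
#'
#' @param trial An [imu_trial].
#' @return A T x 7 numeric matrix of class `emission_matrix` with column
#'   names `gyro_ml, d_gyro_ml, acc_ap, d_acc_ap, d_acc_ml, d_acc_vt,
#'   waist_acc_ml`; attributes `side` and `fs`.
#' @export
build_emission_matrix <- function(trial) {
  fs <- trial$fs
  waist_ml <- trial$waist_acc[, 3]
  if (identical(trial$side, "left")) waist_ml <- -waist_ml
  em <- cbind(
    gyro_ml      = trial$shank_gyro[, 3],
    d_gyro_ml    = approx_derivative(trial$shank_gyro[, 3], fs),
    acc_ap       = trial$shank_acc[, 2],
    d_acc_ap     = approx_derivative(trial$shank_acc[, 2], fs),
    d_acc_ml     = approx_derivative(trial$shank_acc[, 3], fs),
    d_acc_vt     = approx_derivative(trial$shank_acc[, 1], fs),
    waist_acc_ml = waist_ml)
  structure(em, side = trial$side, fs = fs, class = c("emission_matrix",
                                                      class(em)))
}

#' Stance/swing state labels from gait events
#'
#' Samples from a foot strike up to (excluding) the following toe off are
#' stance (0); samples from a toe off up to the next foot strike are swing
#' (1). Samples before the first event and after the last one extend the
#' adjacent phase.
#'
#' @param events A [gait_events] object (1-based indices).
#' @param T Trial length in samples.
#' @return Integer vector of length `T` over \{0 = stance, 1 = swing\}.
#' @export
events_to_states <- function(events, T) {
  validate_gait_events(events, T = T)
  fs <- events$foot_strikes
  to <- events$toe_offs
  states <- integer(T)                  # default stance
  # phase boundaries: at each FS the phase becomes stance, at each TO swing
  ev_idx <- c(fs, to)
  ev_state <- c(rep(0L, length(fs)), rep(1L, length(to)))
  o <- order(ev_idx)
  ev_idx <- ev_idx[o]; ev_state <- ev_state[o]
  # before the first event: extension of the phase that precedes it
  states[seq_len(ev_idx[1] - 1L)] <- 1L - ev_state[1]
  for (k in seq_along(ev_idx)) {
    end <- if (k < length(ev_idx)) ev_idx[k + 1] - 1L else T
    states[ev_idx[k]:end] <- ev_state[k]
  }
  states
}
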