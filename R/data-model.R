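# Domain types: gait events, IMU trials, datasets.
#
# Axis order is fixed everywhere to (VT, AP, ML): vertical (downward),
# antero-posterior (forward), medio-lateral (right). Event indices are 1-based
# sample indices (R convention) into the signal arrays.

AXIS_NAMES <- c("vt", "ap", "ml")

#' Gait event annotations for one trial
#'
#' Foot-strike (FS) and toe-off (TO) sample indices delimiting the stance and
#' swing phases: stance runs from a foot strike to the following toe off,
#' swing from a toe off to the next foot strike. Events must interleave as
#' FS < TO < FS < TO ... and every index must lie within the trial.
#'
#' @param foot_strikes Integer vector of 1-based foot-strike sample indices,
#'   strictly increasing.
#' @param toe_offs Integer vector of 1-based toe-off sample indices, strictly
#'   increasing and interleaving with `foot_strikes`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(foot_strikes, toe_offs) {
  foot_strikes <- as.integer(foot_strikes)
  toe_offs <- as.integer(toe_offs)
  ev <- structure(list(foot_strikes = foot_strikes, toe_offs = toe_offs),
                  class = "gait_events")
  validate_gait_events(ev)
  ev
}

validate_gait_events <- function(ev, T = NULL, what = "events") {
  fs <- ev$foot_strikes
  to <- ev$toe_offs
  if (length(fs) < 1L || length(to) < 1L) {
    stop(what, ": need at least one foot-strike/toe-off pair", call. = FALSE)
  }
  if (is.unsorted(fs, strictly = TRUE) || is.unsorted(to, strictly = TRUE)) {
    stop(what, ": event indices must be strictly increasing", call. = FALSE)
  }
  # Interleaving FS < TO < FS < ...: merge and check alternation starting at FS.
  if (!(length(fs) == length(to) || length(fs) == length(to) + 1L)) {
    stop(what, ": foot strikes and toe offs do not interleave", call. = FALSE)
  }
  n <- length(to)
  if (any(fs[seq_len(n)] >= to) ||
      (length(fs) > 1L && any(to[seq_len(length(fs) - 1L)] >= fs[-1L]))) {
    stop(what, ": events must interleave as FS < TO < FS < TO ...", call. = FALSE)
  }
  if (any(fs < 1L) || any(to < 1L)) {
    stop(what, ": event indices must be >= 1", call. = FALSE)
  }
  if (!is.null(T) && (max(fs, to) > T)) {
    stop(what, ": event index beyond trial length ", T, call. = FALSE)
  }
  invisible(ev)
}

#' One IMU gait trial (a single passage, single body side)
#'
#' Holds the tri-axial shank accelerometer and gyroscope and the tri-axial
#' waist accelerometer for one passage of one subject, together with the
#' sampling rate, side, class label and gold-standard gait events. All signal
#' matrices are T x 3 with fixed column order (VT, AP, ML); accelerations in
#' m/s^2, angular velocities in rad/s.
#'
#' @param subject_id,trial_id Character identifiers.
#' @param side `"left"` or `"right"` — which shank the shank signals come from.
#' @param fs Sampling rate in Hz (the study protocol uses 128 Hz).
#' @param shank_acc,shank_gyro,waist_acc Numeric T x 3 matrices, columns
#'   (VT, AP, ML).
#' @param events A [gait_events] object with 1-based sample indices.
#' @param group_label Optional class label, one of `"EL"`, `"PS"`, `"HD"`
#'   (absent at prediction time).
#' @param impaired_side For post-stroke (`"PS"`) subjects only: `"left"` or
#'   `"right"`, the hemiparetic side.
#' @return An object of class `imu_trial`.
#' @export
imu_trial <- function(subject_id, trial_id, side, fs, shank_acc, shank_gyro,
                      waist_acc, events, group_label = NULL,
                      impaired_side = NULL) {
  tr <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         side = side, fs = fs,
         shank_acc = as.matrix(shank_acc),
         shank_gyro = as.matrix(shank_gyro),
         waist_acc = as.matrix(waist_acc),
         events = events,
         group_label = group_label,
         impaired_side = impaired_side),
    class = "imu_trial")
  validate_imu_trial(tr)
  tr
}

validate_imu_trial <- function(tr) {
  id <- paste0(tr$subject_id, "/", tr$trial_id, "/", tr$side)
  if (!tr$side %in% c("left", "right")) {
    stop("trial ", id, ": side must be 'left' or 'right'", call. = FALSE)
  }
  if (!is.numeric(tr$fs) || tr$fs <= 0) {
    stop("trial ", id, ": fs must be a positive sampling rate", call. = FALSE)
  }
  sigs <- list(shank_acc = tr$shank_acc, shank_gyro = tr$shank_gyro,
               waist_acc = tr$waist_acc)
  T <- nrow(tr$shank_acc)
  for (nm in names(sigs)) {
    if (!is.matrix(sigs[[nm]]) || ncol(sigs[[nm]]) != 3L) {
      stop("trial ", id, ": ", nm, " must be a T x 3 matrix (VT, AP, ML)",
           call. = FALSE)
    }
    if (nrow(sigs[[nm]]) != T) {
      stop("trial ", id, ": signal length mismatch in ", nm, call. = FALSE)
    }
    if (anyNA(sigs[[nm]]) || any(!is.finite(sigs[[nm]]))) {
      stop("trial ", id, ": non-finite values in ", nm, call. = FALSE)
    }
  }
  if (T < 2 * tr$fs) {
    stop("trial ", id, ": signals must span at least 2 s (T >= 2*fs); got T = ",
         T, call. = FALSE)
  }
  if (!is.null(tr$group_label) && !tr$group_label %in% GAIT_CLASSES) {
    stop("trial ", id, ": unknown group label '", tr$group_label, "'",
         call. = FALSE)
  }
  if (!is.null(tr$group_label)) {
    if (identical(tr$group_label, "PS") && is.null(tr$impaired_side)) {
      stop("trial ", id, ": PS trials must carry impaired_side", call. = FALSE)
    }
    if (!identical(tr$group_label, "PS") && !is.null(tr$impaired_side)) {
      stop("trial ", id, ": impaired_side is only valid for PS trials",
           call. = FALSE)
    }
  }
  if (!is.null(tr$impaired_side) && !tr$impaired_side %in% c("left", "right")) {
    stop("trial ", id, ": impaired_side must be 'left' or 'right'", call. = FALSE)
  }
  validate_gait_events(tr$events, T = T, what = paste0("trial ", id, " events"))
  invisible(tr)
}

n_samples <- function(trial) nrow(trial$shank_acc)

#' Bundle IMU trials into a dataset
#'
#' @param trials A list of [imu_trial] objects. Within one subject the group
#'   label must be constant.
#' @return An object of class `gait_dataset` with a `subjects` index
#'   (subject_id -> trial positions).
#' @export
gait_dataset <- function(trials) {
  if (length(trials) == 0L) {
    stop("empty dataset: no trials", call. = FALSE)
  }
  for (tr in trials) validate_imu_trial(tr)
  ids <- vapply(trials, `[[`, character(1), "subject_id")
  subjects <- split(seq_along(trials), ids)
  for (sid in names(subjects)) {
    labs <- unique(vapply(trials[subjects[[sid]]], function(tr) {
      if (is.null(tr$group_label)) NA_character_ else tr$group_label
    }, character(1)))
    if (length(labs) > 1L) {
      stop("subject ", sid, ": inconsistent group labels (",
           paste(labs, collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(trials = trials, subjects = subjects), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  labs <- vapply(x$trials, function(tr) {
    if (is.null(tr$group_label)) "?" else tr$group_label
  }, character(1))
  cat("<gait_dataset>", length(x$trials), "trial-sides,",
      length(x$subjects), "subjects\n")
  print(table(labs))
  invisible(x)
}

# Per-subject label lookup, named character vector (NA when unlabeled).
subject_labels <- function(dataset) {
  vapply(dataset$subjects, function(idx) {
    lab <- dataset$trials[[idx[1]]]$group_label
    if (is.null(lab)) NA_character_ else lab
  }, character(1))
}
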