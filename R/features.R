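# The 90-dimensional hybrid feature vector: six HMM log-likelihood features
# (H1-H6), six time-domain descriptors per channel (T1-T6, 42 values) and six
# frequency-domain descriptors per channel (F1-F6, 42 values), computed on
# the seven emission channels.

TIME_FEATURES <- paste0("T", 1:6)
FREQ_FEATURES <- paste0("F", 1:6)

#' Names and layout of the 90-dimensional feature vector
#'
#' Fixed layout: positions 1-6 are `H1..H6`; positions 7-48 the time-domain
#' features channel-major (`T1_ch1..T6_ch1, T1_ch2, ...`); positions 49-90
#' the frequency-domain features channel-major.
#'
#' @return Character vector of 90 feature names.
#' @export
feature_layout <- function() {
  c(paste0("H", 1:6),
    as.vector(vapply(1:7, function(ch) paste0(TIME_FEATURES, "_ch", ch),
                     character(6))),
    as.vector(vapply(1:7, function(ch) paste0(FREQ_FEATURES, "_ch", ch),
                     character(6))))
}

#' HMM log-likelihood features H1-H6
#'
#' H1-H3 are the log-likelihoods of the observation sequence under the EL, PS
#' and HD models, each restricted to the first 2 s of the passage so all
#' passages are compared over the same window. H4-H6 are the pairwise
#' log-likelihood differences EL-PS, EL-HD and PS-HD evaluated on the whole
#' passage: differencing removes the sequence-length dependence of the
#' log-likelihood, so trials of different duration stay comparable.
#'
#' @param models Named list of `gait_hmm` models (`EL`, `PS`, `HD`).
#' @param emissions An emission matrix (T x 7, T >= 2 s of samples).
#' @param fs Sampling rate in Hz (defaults to the matrix's `fs` attribute).
#' @return Named numeric vector `H1..H6`.
#' @export
hmm_features <- function(models, emissions, fs = attr(emissions, "fs")) {
  win <- 2 * fs
  if (nrow(emissions) < win) {
    stop("passage shorter than the 2-s likelihood window", call. = FALSE)
  }
  ll_win <- vapply(GAIT_CLASSES, function(cls) {
    log_likelihood(models[[cls]], emissions, window_samples = win)
  }, numeric(1))
  ll_full <- vapply(GAIT_CLASSES, function(cls) {
    log_likelihood(models[[cls]], emissions)
  }, numeric(1))
  c(H1 = unname(ll_win["EL"]), H2 = unname(ll_win["PS"]),
    H3 = unname(ll_win["HD"]),
    H4 = unname(ll_full["EL"] - ll_full["PS"]),
    H5 = unname(ll_full["EL"] - ll_full["HD"]),
    H6 = unname(ll_full["PS"] - ll_full["HD"]))
}

#' Time-domain features T1-T6 of one channel
#'
#' Mean, standard deviation, variance, maximum, minimum and range.
#'
#' @param channel Numeric vector (length >= 2).
#' @return Named numeric vector `T1..T6`.
#' @export
time_features <- function(channel) {
  if (length(channel) < 2L) {
    stop("time_features needs at least 2 samples", call. = FALSE)
  }
  c(T1 = mean(channel), T2 = sd(channel), T3 = var(channel),
    T4 = max(channel), T5 = min(channel), T6 = max(channel) - min(channel))
}

#' Frequency-domain features F1-F6 of one channel
#'
#' Raw (untapered) periodogram of the mean-removed channel. F3 is the first
#' dominant frequency (location of the global periodogram maximum, DC
#' excluded) and F1 the power there; F4 is the second dominant frequency —
#' the highest local periodogram maximum at least `min_sep_hz` away from F3 —
#' and F2 its power; F5 is the total power over (0, fs/2]; F6 = F1/F5.
#'
#' An all-constant channel has an empty spectrum: all six features are
#' returned as 0 with a warning. If no separated second peak exists, F2 and
#' F4 are 0.
#'
#' @param channel Numeric vector, length >= 32.
#' @param fs Sampling rate in Hz.
#' @param min_sep_hz Minimum separation between the two dominant peaks
#'   (default 0.2 Hz), preventing the shoulder bin of the main peak from
#'   being reported as a second peak.
#' @return Named numeric vector `F1..F6`.
#' @export
freq_features <- function(channel, fs, min_sep_hz = 0.2) {
  if (length(channel) < 32L) {
    stop("freq_features needs at least 32 samples", call. = FALSE)
  }
  if (max(channel) == min(channel)) {
    warning("constant channel: spectrum is identically zero; ",
            "returning zero frequency features")
    return(c(F1 = 0, F2 = 0, F3 = 0, F4 = 0, F5 = 0, F6 = 0))
  }
  pg <- spec.pgram(channel - mean(channel), taper = 0, detrend = FALSE,
                   demean = FALSE, fast = FALSE, plot = FALSE)
  freq <- pg$freq * fs        # cycles/sample -> Hz
  pow <- pg$spec
  i1 <- which.max(pow)
  f1 <- freq[i1]; p1 <- pow[i1]
  ptot <- sum(pow)
  # local maxima (interior bins strictly above both neighbours; end bins
  # above their single neighbour)
  n <- length(pow)
  is_max <- c(pow[1] > pow[2],
              pow[2:(n - 1)] > pow[1:(n - 2)] & pow[2:(n - 1)] > pow[3:n],
              pow[n] > pow[n - 1])
  cand <- which(is_max & abs(freq - f1) >= min_sep_hz)
  if (length(cand) == 0L) {
    f2 <- 0; p2 <- 0
  } else {
    i2 <- cand[which.max(pow[cand])]
    f2 <- freq[i2]; p2 <- pow[i2]
  }
  c(F1 = p1, F2 = p2, F3 = f1, F4 = f2, F5 = ptot, F6 = p1 / ptot)
}

#' Assemble the 90-dimensional feature vector for a trial
#'
#' Time- and frequency-domain features are computed on the seven emission
#' channels of the (filtered) trial; the HMM features use the supplied
#' class-specific models.
#'
#' @param trial An [imu_trial].
#' @param models Named list of `gait_hmm` models (`EL`, `PS`, `HD`).
#' @param emissions Optional precomputed emission matrix for `trial`.
#' @return A named numeric vector of length 90 in the [feature_layout()]
#'   order, with attributes `subject_id`, `trial_id`, `side`, `group_label`.
#' @export
assemble_features <- function(trial, models, emissions = NULL) {
  if (is.null(emissions)) emissions <- build_emission_matrix(trial)
  h <- hmm_features(models, emissions, fs = trial$fs)
  tf <- as.vector(apply(unclass(emissions), 2, time_features))
  ff <- as.vector(apply(unclass(emissions), 2, freq_features, fs = trial$fs))
  v <- c(h, tf, ff)
  names(v) <- feature_layout()
  stopifnot(length(v) == 90L, all(is.finite(v)))
  structure(v, subject_id = trial$subject_id, trial_id = trial$trial_id,
            side = trial$side, group_label = trial$group_label)
}

#' Feature table for a whole dataset
#'
#' @param dataset A [gait_dataset].
#' @param models Named list of `gait_hmm` models.
#' @param emissions Optional list of precomputed emission matrices, parallel
#'   to `dataset$trials`.
#' @param tf_features Optional precomputed matrix of the 84 time/frequency
#'   columns (they do not depend on `models`, so callers that retrain models
#'   repeatedly can compute them once via [time_freq_features()]).
#' @return A data frame: metadata columns `subject_id`, `trial_id`, `side`,
#'   `group_label` followed by the 90 feature columns.
#' @export
feature_table <- function(dataset, models, emissions = NULL,
                          tf_features = NULL) {
  if (is.null(emissions)) {
    emissions <- lapply(dataset$trials, build_emission_matrix)
  }
  if (is.null(tf_features)) {
    tf_features <- time_freq_features(dataset, emissions)
  }
  h <- t(vapply(seq_along(dataset$trials), function(i) {
    hmm_features(models, emissions[[i]], fs = dataset$trials[[i]]$fs)
  }, numeric(6)))
  meta <- data.frame(
    subject_id = vapply(dataset$trials, `[[`, character(1), "subject_id"),
    trial_id = vapply(dataset$trials, `[[`, character(1), "trial_id"),
    side = vapply(dataset$trials, `[[`, character(1), "side"),
    group_label = vapply(dataset$trials, function(tr) {
      if (is.null(tr$group_label)) NA_character_ else tr$group_label
    }, character(1)))
  cbind(meta, as.data.frame(h), as.data.frame(tf_features))
}

#' The 84 time/frequency feature columns of a dataset
#'
#' @inheritParams feature_table
#' @return Numeric matrix, one row per trial-side, columns `T1_ch1..F6_ch7`.
#' @export
time_freq_features <- function(dataset, emissions = NULL) {
  if (is.null(emissions)) {
    emissions <- lapply(dataset$trials, build_emission_matrix)
  }
  out <- t(vapply(seq_along(dataset$trials), function(i) {
    em <- unclass(emissions[[i]])
    c(as.vector(apply(em, 2, time_features)),
      as.vector(apply(em, 2, freq_features, fs = dataset$trials[[i]]$fs)))
  }, numeric(84)))
  colnames(out) <- feature_layout()[7:90]
  out
}
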