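# Class-specific two-state (stance/swing) hidden Markov model with
# three-mode Gaussian-mixture emissions over the seven observation channels.
# Training is supervised: the gold-standard foot-strike / toe-off annotations
# fix the state sequence, so initial and transition probabilities are
# empirical frequencies and each state's mixture is fitted by EM on the
# frames assigned to that state.

HMM_STATES <- c("stance", "swing")

#' Supervised training of a class-specific gait HMM
#'
#' Initial-state probabilities are the empirical distribution of first-sample
#' states across training sequences; the 2 x 2 transition matrix holds
#' empirical transition frequencies between consecutive samples; each state's
#' three-mode diagonal-covariance Gaussian mixture is fitted by EM (k-means
#' initialization, variance floor, fixed internal seed) on the pooled frames
#' of that state.
#'
#' @param emissions List of emission matrices from [build_emission_matrix()].
#' @param states List of integer state sequences (0 = stance, 1 = swing) from
#'   [events_to_states()], each matching its emission matrix row count.
#' @param class_label The gait class the model represents (`"EL"`, `"PS"`,
#'   `"HD"`), kept as metadata.
#' @param n_modes Number of mixture components per state (default 3).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param floor_frac Variance floor as a fraction of each channel's pooled
#'   training variance.
#' @param seed Internal EM seed (fixed by default so training is
#'   deterministic).
#' @return An object of class `gait_hmm`: `pi`, `A`, per-state mixture
#'   parameters, `class_label`, channel names.
#' @export
train_hmm_supervised <- function(emissions, states, class_label = NULL,
                                 n_modes = 3, max_iter = 200, tol = 1e-6,
                                 floor_frac = 1e-6, seed = 0L) {
  if (length(emissions) == 0L || length(emissions) != length(states)) {
    stop("need a nonempty training set with one state sequence per ",
         "emission matrix", call. = FALSE)
  }
  for (i in seq_along(emissions)) {
    if (nrow(emissions[[i]]) != length(states[[i]])) {
      stop("sequence ", i, ": emission matrix and state sequence lengths ",
           "differ", call. = FALSE)
    }
  }
  D <- ncol(emissions[[1]])

  # empirical initial distribution and transition counts
  first <- vapply(states, `[`, integer(1), 1L)
  pi <- c(sum(first == 0L), sum(first == 1L)) / length(first)
  trans <- matrix(0, 2, 2, dimnames = list(HMM_STATES, HMM_STATES))
  for (st in states) {
    from <- st[-length(st)] + 1L
    to <- st[-1L] + 1L
    trans <- trans + table(factor(from, 1:2), factor(to, 1:2))
  }
  rs <- rowSums(trans)
  if (any(rs == 0)) {
    stop("state '", HMM_STATES[which(rs == 0)[1]],
         "' unobserved in training data", call. = FALSE)
  }
  A <- trans / rs

  pooled <- do.call(rbind, lapply(emissions, unclass))
  all_states <- unlist(states)
  mixtures <- lapply(0:1, function(s) {
    frames <- pooled[all_states == s, , drop = FALSE]
    if (nrow(frames) < n_modes * D) {
      stop("insufficient frames for ", n_modes, "-mode GMM in state '",
           HMM_STATES[s + 1], "' (", nrow(frames), " frames)", call. = FALSE)
    }
    fit_diag_gmm(frames, M = n_modes, max_iter = max_iter, tol = tol,
                 floor_frac = floor_frac, seed = seed)
  })
  names(mixtures) <- HMM_STATES

  structure(list(pi = as.numeric(pi), A = unclass(A), mixtures = mixtures,
                 class_label = class_label, channels = colnames(emissions[[1]]),
                 n_modes = n_modes),
            class = "gait_hmm")
}

# T x 2 matrix of per-state log emission densities.
state_logdens <- function(params, em) {
  matrix(vapply(params$mixtures, function(mx) {
    gmm_logdens(em, mx$weights, mx$means, mx$vars)
  }, numeric(nrow(em))), nrow = nrow(em))
}

#' Log-likelihood of an observation sequence under a gait HMM
#'
#' Exact log of the total observation probability, computed by the scaled
#' forward recursion (per-step normalization, so long sequences cannot
#' underflow).
#'
#' @param params A `gait_hmm` from [train_hmm_supervised()].
#' @param emissions An emission matrix (T x 7).
#' @param window_samples If given, only the first `window_samples` samples are
#'   evaluated (the validation convention uses the first 2 s of a passage).
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(params, emissions, window_samples = NULL) {
  em <- as.matrix(unclass(emissions))
  if (ncol(em) != length(params$channels)) {
    stop("emission matrix has ", ncol(em), " channels; model expects ",
         length(params$channels), call. = FALSE)
  }
  if (anyNA(em) || any(!is.finite(em))) {
    stop("non-finite emission values", call. = FALSE)
  }
  if (!is.null(window_samples)) {
    if (nrow(em) < window_samples) {
      stop("sequence shorter than the requested window (", nrow(em), " < ",
           window_samples, ")", call. = FALSE)
    }
    em <- em[seq_len(window_samples), , drop = FALSE]
  }
  logB <- state_logdens(params, em)
  .forward_loglik_cpp(logB, params$pi, params$A)
}

# Log-sum-exp forward recursion in pure R; must agree with the scaled C++
# recursion (regression-tested).
forward_loglik_logspace <- function(params, em) {
  logB <- state_logdens(params, as.matrix(unclass(em)))
  la <- log(params$pi) + logB[1, ]
  logA <- log(params$A)
  if (nrow(logB) > 1) {
    for (t in 2:nrow(logB)) {
      la <- apply(la + logA, 2, logsumexp) + logB[t, ]
    }
  }
  logsumexp(la)
}

# Backward-recursion total log-likelihood (internal consistency check).
backward_loglik <- function(params, em) {
  logB <- state_logdens(params, as.matrix(unclass(em)))
  .backward_loglik_cpp(logB, params$pi, params$A)
}

#' Maximum-likelihood gait classification of one passage
#'
#' Evaluates the log-likelihood of the observation window under each
#' class-specific HMM and returns the class whose model explains the data
#' best. Ties break deterministically in the fixed class order EL, PS, HD.
#'
#' @param models Named list of `gait_hmm` models, one per class
#'   (`EL`, `PS`, `HD`).
#' @param emissions An emission matrix.
#' @param window_samples Evaluation window length in samples; the default
#'   `2 * fs` (first 2 s of the passage) matches the validation convention.
#' @return A class label.
#' @export
classify_max_likelihood <- function(models, emissions,
                                    window_samples = 2 * attr(emissions, "fs")) {
  missing <- setdiff(GAIT_CLASSES, names(models))
  if (length(missing) > 0L) {
    stop("missing model(s) for class: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ll <- vapply(GAIT_CLASSES, function(cls) {
    log_likelihood(models[[cls]], emissions, window_samples = window_samples)
  }, numeric(1))
  GAIT_CLASSES[which.max(ll)]   # which.max takes the first max: EL < PS < HD
}

#' Write a trained gait HMM to JSON
#'
#' @param params A `gait_hmm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(params, path) {
  obj <- list(
    class_label = params$class_label,
    channels = params$channels,
    n_modes = params$n_modes,
    pi = params$pi,
    A = apply(params$A, 1, as.numeric, simplify = FALSE),
    mixtures = lapply(params$mixtures, function(mx) {
      list(weights = as.numeric(mx$weights),
           means = apply(mx$means, 1, as.numeric, simplify = FALSE),
           vars = apply(mx$vars, 1, as.numeric, simplify = FALSE))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a gait HMM written by [write_hmm()]
#'
#' @param path JSON file path.
#' @return A `gait_hmm`.
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  mixtures <- lapply(obj$mixtures, function(mx) {
    list(weights = as.numeric(mx$weights),
         means = as_mat(mx$means),
         vars = as_mat(mx$vars))
  })
  structure(list(pi = as.numeric(obj$pi),
                 A = as_mat(obj$A),
                 mixtures = mixtures,
                 class_label = obj$class_label,
                 channels = obj$channels,
                 n_modes = obj$n_modes),
            class = "gait_hmm")
}
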