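# Independent oracles and small fixture builders used across the suite.

# Exhaustive-path log-likelihood: sum over all S^T hidden-state paths of
# pi[s1] * prod A * prod emission densities. Exponential cost; only for
# T <= ~8.
brute_force_loglik <- function(params, em) {
  em <- as.matrix(unclass(em))
  T <- nrow(em)
  S <- length(params$pi)
  dens <- sapply(params$mixtures, function(mx) {
    vapply(seq_len(T), function(t) {
      sum(vapply(seq_along(mx$weights), function(m) {
        mx$weights[m] * prod(stats::dnorm(em[t, ], mx$means[m, ],
                                          sqrt(mx$vars[m, ])))
      }, numeric(1)))
    }, numeric(1))
  })
  dens <- matrix(dens, nrow = T)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- params$pi[paths[r, 1]] * dens[1, paths[r, 1]]
    if (T > 1) for (t in 2:T) {
      p <- p * params$A[paths[r, t - 1], paths[r, t]] * dens[t, paths[r, t]]
    }
    total <- total + p
  }
  log(total)
}

# Random two-state gait_hmm with M diagonal-Gaussian modes in D dims.
random_hmm <- function(D = 7, M = 3) {
  rand_simplex <- function(n) {
    x <- stats::runif(n, 0.2, 1)
    x / sum(x)
  }
  mixtures <- lapply(1:2, function(s) {
    list(weights = rand_simplex(M),
         means = matrix(stats::rnorm(M * D, sd = 2), M, D),
         vars = matrix(stats::runif(M * D, 0.2, 2), M, D))
  })
  names(mixtures) <- c("stance", "swing")
  A <- rbind(rand_simplex(2), rand_simplex(2))
  structure(list(pi = rand_simplex(2), A = A, mixtures = mixtures,
                 class_label = NULL,
                 channels = paste0("ch", seq_len(D)), n_modes = M),
            class = "gait_hmm")
}

# Draw an emission sequence and its state path from a gait_hmm.
simulate_hmm_sequence <- function(params, T) {
  S <- length(params$pi)
  D <- ncol(params$mixtures[[1]]$means)
  states <- integer(T)
  em <- matrix(0, T, D)
  s <- sample.int(S, 1, prob = params$pi)
  for (t in seq_len(T)) {
    states[t] <- s
    mx <- params$mixtures[[s]]
    m <- sample.int(length(mx$weights), 1, prob = mx$weights)
    em[t, ] <- stats::rnorm(D, mx$means[m, ], sqrt(mx$vars[m, ]))
    if (t < T) s <- sample.int(S, 1, prob = params$A[s, ])
  }
  colnames(em) <- params$channels
  list(emissions = em, states = states - 1L)
}

# Minimal valid trial with analytically known content: every signal column
# is filled from `filler(T)` unless overridden.
make_trial <- function(T = 300, fs = 128, side = "right", group = "EL",
                       impaired = NULL, filler = function(T) sin(seq_len(T) / 10),
                       waist_ml = NULL,
                       events = NULL) {
  base <- matrix(filler(T), T, 3)
  waist <- base
  if (!is.null(waist_ml)) waist[, 3] <- waist_ml
  if (is.null(events)) {
    events <- gait_events(c(1, 151), c(101, 251))
  }
  imu_trial(subject_id = "s1", trial_id = "t1", side = side, fs = fs,
            shank_acc = base, shank_gyro = base, waist_acc = waist,
            events = events, group_label = group, impaired_side = impaired)
}

# Small strongly separated cohort configs used by several tests.
small_cohort <- function(n = c(EL = 3, PS = 3, HD = 3), seed = 1,
                         passages = c(2, 3), strides = c(3, 4), ...) {
  cohort_config(n_subjects = n, passages = passages, strides = strides,
                seed = seed, ...)
}

fast_svm_config <- function(...) {
  svm_config(C_grid = 2^c(1, 7), gamma_grid = 2^c(-9, -5), ...)
}
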