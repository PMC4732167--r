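# HMM engine: supervised training, forward recursion, classification.

test_that("supervised training recovers empirical pi and A from counts", {
  # hand-built state sequences with known transition counts
  s1 <- c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L)   # 0->0:3, 0->1:2, 1->0:1, 1->1:1
  s2 <- c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 0L)   # 0->0:1, 0->1:1, 1->0:2, 1->1:3
  set.seed(1)
  e1 <- matrix(rnorm(8 * 2), 8, 2); e2 <- matrix(rnorm(8 * 2), 8, 2)
  colnames(e1) <- colnames(e2) <- c("a", "b")
  m <- train_hmm_supervised(list(e1, e2), list(s1, s2), n_modes = 1)
  expect_equal(m$pi, c(0.5, 0.5))
  expect_equal(unname(m$A[1, ]), c(4 / 7, 3 / 7))
  expect_equal(unname(m$A[2, ]), c(3 / 7, 4 / 7))
  expect_equal(rowSums(m$A), c(stance = 1, swing = 1), tolerance = 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
})

test_that("training is invariant to the order of training sequences", {
  set.seed(2)
  seqs <- lapply(1:4, function(i) {
    T <- 40 + i
    list(em = matrix(rnorm(T * 3), T, 3),
         st = rep(rep(0:1, 10), length.out = T))
  })
  m1 <- train_hmm_supervised(lapply(seqs, `[[`, "em"),
                             lapply(seqs, `[[`, "st"))
  m2 <- train_hmm_supervised(lapply(rev(seqs), `[[`, "em"),
                             lapply(rev(seqs), `[[`, "st"))
  expect_identical(m1$A, m2$A)
  expect_identical(m1$pi, m2$pi)
})

test_that("degenerate training sets are rejected", {
  em <- matrix(rnorm(600 * 2), 600, 2)
  expect_error(train_hmm_supervised(list(em), list(rep(0L, 600))),
               "unobserved")
  expect_error(train_hmm_supervised(list(), list()), "nonempty")
  expect_error(train_hmm_supervised(list(em), list(rep(0L, 10))), "lengths")
  # too few frames in one state for a 3-mode mixture of 2 channels
  st <- c(rep(0L, 596), rep(1L, 4))
  expect_error(train_hmm_supervised(list(em), list(st)), "insufficient frames")
})

test_that("HMMParams invariants hold after training on generated gait", {
  ds <- generate_cohort(small_cohort(n = c(EL = 2), seed = 12))
  ems <- lapply(ds$trials, build_emission_matrix)
  sts <- lapply(ds$trials, function(tr) events_to_states(tr$events,
                                                         n_samples(tr)))
  m <- train_hmm_supervised(ems, sts, class_label = "EL")
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m$A)), c(1, 1), tolerance = 1e-12)
  for (mx in m$mixtures) {
    expect_equal(sum(mx$weights), 1, tolerance = 1e-12)
    expect_true(all(sweep(mx$vars, 2, mx$variance_floor, `>=`)))
  }
})

test_that("scaled forward log-likelihood matches exhaustive path enumeration", {
  set.seed(123)
  for (rep in 1:25) {
    D <- sample(1:3, 1)
    hmm <- random_hmm(D = D, M = sample(1:3, 1))
    T <- sample(1:6, 1)
    em <- matrix(rnorm(T * D, sd = 2), T, D)
    expect_equal(log_likelihood(hmm, em), brute_force_loglik(hmm, em),
                 tolerance = 1e-9)
  }
})

test_that("scaled, log-space and backward recursions agree", {
  set.seed(321)
  for (rep in 1:10) {
    hmm <- random_hmm(D = 2, M = 2)
    em <- matrix(rnorm(200 * 2), 200, 2)
    ll <- log_likelihood(hmm, em)
    expect_equal(ll, forward_loglik_logspace(hmm, em), tolerance = 1e-9)
    expect_equal(ll, backward_loglik(hmm, em), tolerance = 1e-8)
  }
})

test_that("a single-sample sequence reduces to the state density", {
  set.seed(5)
  hmm <- random_hmm(D = 2, M = 3)
  hmm$pi <- c(1, 0)
  hmm$A <- diag(2)
  x <- rnorm(2)
  mx <- hmm$mixtures$stance
  expected <- log(sum(vapply(1:3, function(m) {
    mx$weights[m] * prod(dnorm(x, mx$means[m, ], sqrt(mx$vars[m, ])))
  }, numeric(1))))
  expect_equal(log_likelihood(hmm, matrix(x, 1, 2)), expected,
               tolerance = 1e-12)
})

test_that("likelihood is invariant to mixture component relabeling", {
  set.seed(6)
  hmm <- random_hmm(D = 3, M = 3)
  em <- matrix(rnorm(50 * 3), 50, 3)
  ll <- log_likelihood(hmm, em)
  perm <- c(3, 1, 2)
  hmm2 <- hmm
  for (s in 1:2) {
    hmm2$mixtures[[s]]$weights <- hmm$mixtures[[s]]$weights[perm]
    hmm2$mixtures[[s]]$means <- hmm$mixtures[[s]]$means[perm, ]
    hmm2$mixtures[[s]]$vars <- hmm$mixtures[[s]]$vars[perm, ]
  }
  expect_equal(log_likelihood(hmm2, em), ll, tolerance = 1e-12)
})

test_that("windowed evaluation uses exactly the first window_samples", {
  set.seed(7)
  hmm <- random_hmm(D = 2, M = 2)
  em <- matrix(rnorm(100 * 2), 100, 2)
  expect_equal(log_likelihood(hmm, em, window_samples = 40),
               log_likelihood(hmm, em[1:40, ]))
  expect_error(log_likelihood(hmm, em, window_samples = 101), "shorter")
  em[3, 1] <- NA
  expect_error(log_likelihood(hmm, em), "non-finite")
})

test_that("the generating model wins on average (Gibbs inequality)", {
  set.seed(8)
  gen <- random_hmm(D = 2, M = 1)
  other <- random_hmm(D = 2, M = 1)
  diffs <- replicate(30, {
    em <- simulate_hmm_sequence(gen, 80)$emissions
    log_likelihood(gen, em) - log_likelihood(other, em)
  })
  expect_gt(mean(diffs), 0)
})

test_that("max-likelihood classification is deterministic with EL tie-break", {
  set.seed(9)
  hmm <- random_hmm(D = 7, M = 2)
  em <- matrix(rnorm(300 * 7), 300, 7)
  attr(em, "fs") <- 128
  models <- list(EL = hmm, PS = hmm, HD = hmm)
  expect_identical(classify_max_likelihood(models, em, window_samples = 256),
                   "EL")
  expect_error(classify_max_likelihood(models[c("EL", "PS")], em),
               "missing model")
})

test_that("well-separated classes are recovered by max-likelihood", {
  set.seed(10)
  mk <- function(shift) {
    h <- random_hmm(D = 2, M = 1)
    h$mixtures$stance$means[] <- shift
    h$mixtures$swing$means[] <- shift + 1
    h$mixtures$stance$vars[] <- 0.3
    h$mixtures$swing$vars[] <- 0.3
    h
  }
  models <- list(EL = mk(-4), PS = mk(0), HD = mk(4))
  hits <- vapply(1:40, function(i) {
    cls <- sample(c("EL", "PS", "HD"), 1)
    em <- simulate_hmm_sequence(models[[cls]], 60)$emissions
    classify_max_likelihood(models, em, window_samples = 60) == cls
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trained models serialize to JSON and back without loss", {
  ds <- generate_cohort(small_cohort(n = c(EL = 2), seed = 13))
  ems <- lapply(ds$trials, build_emission_matrix)
  sts <- lapply(ds$trials, function(tr) events_to_states(tr$events,
                                                         n_samples(tr)))
  m <- train_hmm_supervised(ems, sts, class_label = "EL")
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_equal(m2$pi, m$pi)
  expect_equal(m2$A, m$A, ignore_attr = TRUE)
  expect_equal(log_likelihood(m2, ems[[1]]), log_likelihood(m, ems[[1]]))
})
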