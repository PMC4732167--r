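# The 90-dimensional feature set.

trained_small_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_cohort(small_cohort(seed = 50))
      ems <- lapply(ds$trials, build_emission_matrix)
      sts <- lapply(ds$trials, function(tr) {
        events_to_states(tr$events, n_samples(tr))
      })
      labs <- vapply(ds$trials, `[[`, character(1), "group_label")
      models <- lapply(c(EL = "EL", PS = "PS", HD = "HD"), function(cls) {
        train_hmm_supervised(ems[labs == cls], sts[labs == cls], cls)
      })
      cache <<- list(ds = ds, models = models)
    }
    cache
  }
})

test_that("time features compute the six descriptors and their identities", {
  expect_equal(unname(time_features(c(1, 1, 1, 1))), c(1, 0, 0, 1, 1, 0))
  f <- time_features(c(0, 2))
  expect_equal(unname(f[c("T1", "T4", "T5", "T6")]), c(1, 2, 0, 2))
  set.seed(60)
  x <- rnorm(100)
  f <- time_features(x)
  expect_equal(unname(f["T3"]), unname(f["T2"])^2, tolerance = 1e-9)
  expect_equal(unname(f["T6"]), unname(f["T4"] - f["T5"]), tolerance = 1e-12)
  expect_error(time_features(numeric(0)), "at least 2")
})

test_that("frequency features find the dominant tones of a known mixture", {
  fs <- 128
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x1 <- sin(2 * pi * 1 * t)
  f <- freq_features(x1, fs)
  expect_equal(unname(f["F3"]), 1, tolerance = fs / length(t) + 1e-9)
  # two tones: 1 Hz (amp 2) dominates 3 Hz (amp 1)
  x2 <- 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
  f2 <- freq_features(x2, fs)
  expect_equal(unname(f2["F3"]), 1, tolerance = 0.2)
  expect_equal(unname(f2["F4"]), 3, tolerance = 0.2)
  expect_gt(f2[["F1"]], f2[["F2"]])
  expect_gte(f2[["F6"]], 0); expect_lte(f2[["F6"]], 1)
  set.seed(61)
  f3 <- freq_features(rnorm(512), fs)
  expect_gte(f3[["F6"]], 0); expect_lte(f3[["F6"]], 1)
})

test_that("a constant channel yields zero frequency features with a warning", {
  expect_warning(f <- freq_features(rep(2, 100), 128), "constant channel")
  expect_equal(unname(f), rep(0, 6))
})

test_that("channel rescaling moves the features the way units demand", {
  set.seed(62)
  x <- rnorm(512) + sin(2 * pi * 1.3 * seq_len(512) / 128)
  c0 <- 3.7
  tf1 <- time_features(x); tf2 <- time_features(c0 * x)
  expect_equal(unname(tf2[c("T2", "T4", "T5", "T6")]),
               c0 * unname(tf1[c("T2", "T4", "T5", "T6")]), tolerance = 1e-9)
  expect_equal(unname(tf2["T3"]), c0^2 * unname(tf1["T3"]), tolerance = 1e-9)
  ff1 <- freq_features(x, 128); ff2 <- freq_features(c0 * x, 128)
  expect_equal(unname(ff2[c("F1", "F2", "F5")]),
               c0^2 * unname(ff1[c("F1", "F2", "F5")]), tolerance = 1e-9)
  expect_equal(unname(ff2[c("F3", "F4", "F6")]),
               unname(ff1[c("F3", "F4", "F6")]), tolerance = 1e-12)
})

test_that("H features: windows, differences and algebraic identities", {
  fx <- trained_small_models()
  tr <- fx$ds$trials[[1]]
  em <- build_emission_matrix(tr)
  h <- hmm_features(fx$models, em, fs = tr$fs)
  expect_named(h, paste0("H", 1:6))
  # H1-H3 are the 2-s window log-likelihoods
  expect_equal(h[["H1"]], log_likelihood(fx$models$EL, em,
                                         window_samples = 2 * tr$fs))
  # H4 - H5 + H6 = 0 identically
  expect_equal(h[["H4"]] - h[["H5"]] + h[["H6"]], 0, tolerance = 1e-9)
  # identical models make the differences exactly zero
  same <- list(EL = fx$models$EL, PS = fx$models$EL, HD = fx$models$EL)
  h0 <- hmm_features(same, em, fs = tr$fs)
  expect_identical(h0[["H4"]], 0)
  expect_equal(h0[["H2"]], h0[["H1"]])
  # and H4 stays zero no matter the sequence length
  em2 <- build_emission_matrix(fx$ds$trials[[3]])
  expect_identical(hmm_features(same, em2, fs = tr$fs)[["H4"]], 0)
})

test_that("assembled vectors have the fixed 90-entry layout", {
  fx <- trained_small_models()
  tr <- fx$ds$trials[[2]]
  v <- assemble_features(tr, fx$models)
  expect_length(v, 90L)
  expect_identical(names(v), feature_layout())
  expect_true(all(is.finite(v)))
  expect_identical(sum(startsWith(names(v), "H")), 6L)
  expect_identical(length(grep("^[TF][1-6]_ch[1-7]$", names(v))), 84L)
  # layout is bijective
  expect_identical(anyDuplicated(feature_layout()), 0L)
  # determinism
  expect_identical(assemble_features(tr, fx$models), v)
  # per-channel identities hold inside the assembled vector
  for (ch in 1:7) {
    expect_equal(v[[paste0("T3_ch", ch)]], v[[paste0("T2_ch", ch)]]^2,
                 tolerance = 1e-9)
    expect_equal(v[[paste0("T6_ch", ch)]],
                 v[[paste0("T4_ch", ch)]] - v[[paste0("T5_ch", ch)]],
                 tolerance = 1e-12)
    expect_gte(v[[paste0("F6_ch", ch)]], 0)
    expect_lte(v[[paste0("F6_ch", ch)]], 1)
  }
})

test_that("feature_table matches assemble_features row by row", {
  fx <- trained_small_models()
  ft <- feature_table(fx$ds, fx$models)
  expect_identical(nrow(ft), length(fx$ds$trials))
  i <- 5L
  v <- assemble_features(fx$ds$trials[[i]], fx$models)
  expect_equal(unlist(ft[i, feature_layout()]), v, ignore_attr = TRUE)
})
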