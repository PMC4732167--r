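# Domain types, validation and disk round trips.

test_that("gait events must interleave strictly as FS < TO < FS ...", {
  expect_s3_class(gait_events(c(1, 100), c(50, 150)), "gait_events")
  expect_error(gait_events(c(100, 1), c(50, 150)), "increasing")
  expect_error(gait_events(c(1, 40), c(50, 150)), "interleave")
  expect_error(gait_events(integer(0), 50), "at least one")
  expect_error(gait_events(c(1, 100, 200), c(50, 150, 250, 300)),
               "interleave")
})

test_that("trial validation enforces shapes, lengths and label coherence", {
  expect_s3_class(make_trial(), "imu_trial")
  expect_error(make_trial(T = 100), "2 s")             # < 2*fs samples
  expect_error(make_trial(group = "PS"), "impaired_side")
  expect_s3_class(make_trial(group = "PS", impaired = "left"), "imu_trial")
  expect_error(make_trial(group = "EL", impaired = "left"), "only valid")
  expect_error(make_trial(events = gait_events(1, 400)), "beyond trial")
  tr <- make_trial()
  tr$shank_gyro <- tr$shank_gyro[-1, ]
  expect_error(validate_imu_trial(tr), "mismatch")
})

test_that("a subject cannot carry two different group labels", {
  t1 <- make_trial(); t2 <- make_trial()
  t2$trial_id <- "t2"; t2$group_label <- "HD"
  expect_error(gait_dataset(list(t1, t2)), "inconsistent group labels")
})

test_that("dataset round-trips through the CSV + manifest layout", {
  dir <- withr::local_tempdir()
  ds <- generate_cohort(small_cohort(n = c(EL = 1, PS = 1, HD = 1),
                                     passages = c(2, 2), seed = 3))
  manifest <- write_dataset(ds, dir)
  ds2 <- load_dataset(manifest)
  expect_equal(length(ds2$trials), length(ds$trials))
  # align by identity triple
  key <- function(d) vapply(d$trials, function(tr) {
    paste(tr$subject_id, tr$trial_id, tr$side)
  }, character(1))
  idx <- match(key(ds), key(ds2))
  for (i in seq_along(ds$trials)) {
    a <- ds$trials[[i]]; b <- ds2$trials[[idx[i]]]
    expect_equal(a$shank_acc, b$shank_acc, ignore_attr = TRUE)
    expect_equal(a$waist_acc, b$waist_acc, ignore_attr = TRUE)
    expect_equal(a$events$foot_strikes, b$events$foot_strikes)
    expect_equal(a$events$toe_offs, b$events$toe_offs)
    expect_identical(a$group_label, b$group_label)
    expect_identical(a$impaired_side, b$impaired_side)
  }
})

test_that("loader reports malformed manifests and trials by name", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(fs = 128, trials = list()),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_dataset(file.path(dir, "manifest.json")), "empty dataset")

  ds <- generate_cohort(small_cohort(n = c(EL = 1, PS = 1, HD = 1), seed = 4))
  manifest <- write_dataset(ds, dir)
  man <- jsonlite::read_json(manifest)
  man$trials[[1]]$events$to_idx <- rev(man$trials[[1]]$events$to_idx)
  jsonlite::write_json(man, manifest, auto_unbox = TRUE)
  expect_error(load_dataset(manifest), "increasing|interleave")

  man <- jsonlite::read_json(write_dataset(ds, dir))
  df <- read.csv(file.path(dir, man$trials[[1]]$csv))
  df$shank_acc_vt <- NULL
  write.csv(df, file.path(dir, man$trials[[1]]$csv), row.names = FALSE)
  expect_error(load_dataset(file.path(dir, "manifest.json")),
               "missing column")
})

test_that("save_results writes conserving confusion matrices and reloads", {
  dir <- withr::local_tempdir()
  ds <- generate_cohort(small_cohort(seed = 5))
  res <- loso_evaluate(ds, svm_cfg = fast_svm_config())
  files <- save_results(res, dir)
  expect_true(all(file.exists(file.path(dir, c("passage_predictions.csv",
                                               "vote_tallies.csv",
                                               "confusion_matrices.json")))))
  reread <- jsonlite::read_json(file.path(dir, "confusion_matrices.json"),
                                simplifyVector = TRUE)
  for (nm in names(res$confusion)) {
    counts <- do.call(rbind, reread[[nm]]$counts)
    expect_equal(sum(counts), nrow(res$predictions))
    expect_equal(reread[[nm]]$overall_accuracy,
                 res$confusion[[nm]]$overall_accuracy)
  }
  preds <- read.csv(file.path(dir, "passage_predictions.csv"))
  expect_equal(nrow(preds), nrow(res$predictions))
  expect_equal(preds$predicted_svm_full, res$predictions$predicted_svm_full)
})
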