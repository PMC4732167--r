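# On-disk layout: one CSV per trial-side (one row per sample, columns
# <sensor>_<axis>) plus a JSON manifest listing trials, labels and events.
# Event indices are 0-based on disk (language-neutral) and 1-based in memory.

TRIAL_CSV_COLUMNS <- paste(rep(c("shank_acc", "shank_gyro", "waist_acc"), each = 3),
                           rep(AXIS_NAMES, 3), sep = "_")

#' Load a gait dataset from a JSON manifest
#'
#' Reads the manifest, loads each trial's CSV signal file, validates the trial
#' invariants (equal signal lengths, interleaving events, in-range indices) and
#' applies the standard 5 Hz zero-phase low-pass filter to every signal unless
#' the manifest marks the trial `prefiltered`.
#'
#' @param manifest_path Path to the manifest JSON. CSV paths inside the
#'   manifest are resolved relative to the manifest's directory.
#' @return A [gait_dataset].
#' @seealso [write_dataset()] for the inverse operation.
#' @export
load_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  if (length(man$trials) == 0L) {
    stop("empty dataset: manifest lists no trials", call. = FALSE)
  }
  root <- dirname(manifest_path)
  default_fs <- if (!is.null(man$fs)) man$fs else 128
  trials <- lapply(man$trials, function(entry) {
    id <- paste0(entry$subject_id, "/", entry$trial_id, "/", entry$side)
    csv_path <- file.path(root, entry$csv)
    if (!file.exists(csv_path)) {
      stop("trial ", id, ": signal file not found: ", entry$csv, call. = FALSE)
    }
    df <- read.csv(csv_path)
    missing <- setdiff(TRIAL_CSV_COLUMNS, names(df))
    if (length(missing) > 0L) {
      stop("trial ", id, ": missing column(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    fs <- if (!is.null(entry$fs)) entry$fs else default_fs
    ev <- gait_events(unlist(entry$events$fs_idx) + 1L,
                      unlist(entry$events$to_idx) + 1L)
    tr <- imu_trial(
      subject_id = entry$subject_id, trial_id = entry$trial_id,
      side = entry$side, fs = fs,
      shank_acc = as.matrix(df[paste0("shank_acc_", AXIS_NAMES)]),
      shank_gyro = as.matrix(df[paste0("shank_gyro_", AXIS_NAMES)]),
      waist_acc = as.matrix(df[paste0("waist_acc_", AXIS_NAMES)]),
      events = ev,
      group_label = entry$group_label,
      impaired_side = entry$impaired_side)
    if (is.null(entry$prefiltered) || !isTRUE(entry$prefiltered)) {
      tr <- filter_trial(tr)
    }
    tr
  })
  gait_dataset(trials)
}

#' Write a gait dataset to the CSV + manifest layout
#'
#' @param dataset A [gait_dataset].
#' @param out_dir Output directory (created if needed); one CSV per trial-side
#'   plus `manifest.json`.
#' @param prefiltered Logical flag written into the manifest; `TRUE` (default)
#'   records that signals were already low-pass filtered so [load_dataset()]
#'   will not filter them again.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir, prefiltered = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset$trials, function(tr) {
    stem <- paste(tr$subject_id, tr$trial_id, tr$side, sep = "_")
    csv <- paste0(stem, ".csv")
    df <- data.frame(tr$shank_acc, tr$shank_gyro, tr$waist_acc)
    names(df) <- TRIAL_CSV_COLUMNS
    write.csv(df, file.path(out_dir, csv), row.names = FALSE)
    entry <- list(subject_id = tr$subject_id, trial_id = tr$trial_id,
                  side = tr$side, fs = tr$fs, csv = csv,
                  prefiltered = prefiltered,
                  events = list(fs_idx = tr$events$foot_strikes - 1L,
                                to_idx = tr$events$toe_offs - 1L))
    if (!is.null(tr$group_label)) entry$group_label <- tr$group_label
    if (!is.null(tr$impaired_side)) entry$impaired_side <- tr$impaired_side
    entry
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(fs = dataset$trials[[1]]$fs, trials = entries),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Save evaluation results to disk
#'
#' Writes the per-passage prediction stream(s) as CSV, the subject-level vote
#' tallies as CSV, and the confusion matrices with their accuracies as JSON.
#'
#' @param results A `loso_result` from [loso_evaluate()] (optionally carrying
#'   majority-vote summaries from [majority_vote()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
save_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  pred_path <- file.path(out_dir, "passage_predictions.csv")
  write.csv(results$predictions, pred_path, row.names = FALSE)
  written <- c(written, pred_path)

  cms <- lapply(results$confusion, unclass_confusion)
  if (!is.null(results$vote)) {
    tally_path <- file.path(out_dir, "vote_tallies.csv")
    tallies <- do.call(rbind, lapply(names(results$vote), function(strategy) {
      tl <- results$vote[[strategy]]$tallies
      tl$strategy <- strategy
      tl
    }))
    write.csv(tallies, tally_path, row.names = FALSE)
    written <- c(written, tally_path)
    cms <- c(cms, stats::setNames(
      lapply(results$vote, function(v) unclass_confusion(v$confusion)),
      paste0(names(results$vote), "_mv")))
  }
  cm_path <- file.path(out_dir, "confusion_matrices.json")
  jsonlite::write_json(cms, cm_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, cm_path)
  invisible(written)
}

unclass_confusion <- function(cm) {
  list(counts = apply(cm$counts, 1, as.integer, simplify = FALSE),
       actual = rownames(cm$counts), predicted = colnames(cm$counts),
       overall_accuracy = cm$overall_accuracy,
       class_accuracy = as.list(cm$class_accuracy))
}
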