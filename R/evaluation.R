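# Leave-one-subject-out evaluation of the full pipeline and majority-voting
# post-processing. Four prediction streams are produced per held-out subject:
# maximum-likelihood HMM classification and the SVM on three feature subsets
# (HMM features only, time/frequency features only, full 90-dim set).

PREDICTION_STREAMS <- c("hmm_maxll", "svm_hmm", "svm_timefreq", "svm_full")

new_confusion <- function(counts) {
  base <- sub("^PS.*", "PS", rownames(counts))
  correct <- vapply(seq_len(nrow(counts)),
                    function(i) counts[i, base[i]], numeric(1))
  structure(list(
    counts = counts,
    overall_accuracy = sum(correct) / sum(counts),
    class_accuracy = stats::setNames(correct / rowSums(counts),
                                     rownames(counts))),
    class = "gait_confusion")
}

#' @export
print.gait_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

# Actual-row label: EL / HD, PS split into impaired / not-impaired side.
actual_row_label <- function(true_label, side, impaired_side) {
  ifelse(true_label == "PS",
         ifelse(side == impaired_side, "PS-imp", "PS-notimp"),
         true_label)
}

CONFUSION_ROW_ORDER <- c("EL", "PS-notimp", "PS-imp", "HD")

confusion_from_predictions <- function(actual_rows, predicted) {
  rows <- CONFUSION_ROW_ORDER[CONFUSION_ROW_ORDER %in% actual_rows]
  counts <- table(factor(actual_rows, levels = rows),
                  factor(predicted, levels = GAIT_CLASSES))
  new_confusion(unclass(as.matrix(counts)))
}

#' Leave-one-subject-out evaluation of the gait classification pipeline
#'
#' For each held-out subject, the three class-specific HMMs and the SVM
#' classifiers are trained on the remaining subjects only; every (passage,
#' side) of the held-out subject is then classified by (a) maximum HMM
#' log-likelihood over the first 2 s and (b) the RBF SVM on each of three
#' feature subsets: HMM features only, time/frequency features only, and the
#' full 90-dimensional set.
#'
#' @param dataset A labeled [gait_dataset] with at least 3 subjects per class
#'   (so every training fold keeps >= 2 per class).
#' @param svm_cfg An [svm_config()].
#' @param hmm_modes Mixture components per HMM state (default 3).
#' @param vote Apply [majority_vote()] to every stream and attach the
#'   subject-level summaries (default `TRUE`).
#' @param progress Print one line per fold.
#' @return An object of class `loso_result`: `predictions` (one row per
#'   trial-side with the four predicted labels), `confusion` (per-passage
#'   confusion matrix per stream) and, if `vote`, `vote` (per-stream tallies
#'   and subject-level confusion matrices).
#' @export
loso_evaluate <- function(dataset, svm_cfg = svm_config(), hmm_modes = 3,
                          vote = TRUE, progress = FALSE) {
  labels <- subject_labels(dataset)
  if (anyNA(labels)) {
    stop("all subjects must carry group labels for LOSO evaluation",
         call. = FALSE)
  }
  n_per_class <- table(factor(labels, levels = GAIT_CLASSES))
  for (cls in GAIT_CLASSES) {
    if (n_per_class[[cls]] >= 1L && n_per_class[[cls]] < 3L) {
      stop("LOSO fold would leave class ", cls, " with fewer than 2 ",
           "subjects (", n_per_class[[cls]], " in dataset)", call. = FALSE)
    }
  }

  trials <- dataset$trials
  meta <- data.frame(
    subject_id = vapply(trials, `[[`, character(1), "subject_id"),
    trial_id = vapply(trials, `[[`, character(1), "trial_id"),
    side = vapply(trials, `[[`, character(1), "side"),
    true_label = vapply(trials, `[[`, character(1), "group_label"),
    impaired_side = vapply(trials, function(tr) {
      if (is.null(tr$impaired_side)) NA_character_ else tr$impaired_side
    }, character(1)))

  emissions <- lapply(trials, build_emission_matrix)
  states <- lapply(trials, function(tr) {
    events_to_states(tr$events, n_samples(tr))
  })
  tf <- time_freq_features(dataset, emissions)   # model-independent: cache

  # Holding out subject s only changes the HMM of s's own class, so per
  # class there are just n_class + 1 distinct models (each leave-one-out
  # variant plus the all-subjects model used when s belongs to another
  # class). Train each once and cache its per-trial log-likelihoods (2-s
  # window and full passage).
  ll_cache <- list()
  for (cls in GAIT_CLASSES) {
    cls_subjects <- names(labels)[labels == cls]
    for (variant in c("__all__", cls_subjects)) {
      idx <- which(meta$true_label == cls & meta$subject_id != variant)
      model <- train_hmm_supervised(emissions[idx], states[idx],
                                    class_label = cls, n_modes = hmm_modes)
      lls <- vapply(seq_along(trials), function(i) {
        c(win = log_likelihood(model, emissions[[i]],
                               window_samples = 2 * trials[[i]]$fs),
          full = log_likelihood(model, emissions[[i]]))
      }, numeric(2))
      ll_cache[[cls]][[variant]] <- lls
      if (progress) cat("trained", cls, "model, holding out", variant, "\n")
    }
  }

  preds <- matrix(NA_character_, length(trials), length(PREDICTION_STREAMS),
                  dimnames = list(NULL, PREDICTION_STREAMS))
  for (sid in names(dataset$subjects)) {
    if (progress) cat("LOSO fold: holding out", sid, "\n")
    test_rows <- meta$subject_id == sid
    train_rows <- !test_rows

    lls <- lapply(GAIT_CLASSES, function(cls) {
      variant <- if (labels[[sid]] == cls) sid else "__all__"
      ll_cache[[cls]][[variant]]
    })
    names(lls) <- GAIT_CLASSES
    h <- cbind(H1 = lls$EL["win", ], H2 = lls$PS["win", ],
               H3 = lls$HD["win", ],
               H4 = lls$EL["full", ] - lls$PS["full", ],
               H5 = lls$EL["full", ] - lls$HD["full", ],
               H6 = lls$PS["full", ] - lls$HD["full", ])
    feats <- cbind(h, tf)

    preds[test_rows, "hmm_maxll"] <-
      GAIT_CLASSES[max.col(h[test_rows, 1:3, drop = FALSE],
                           ties.method = "first")]
    subsets <- list(svm_hmm = 1:6, svm_timefreq = 7:90, svm_full = 1:90)
    for (nm in names(subsets)) {
      clf <- grid_search_train(feats[train_rows, subsets[[nm]], drop = FALSE],
                               meta$true_label[train_rows],
                               meta$subject_id[train_rows], svm_cfg)
      preds[test_rows, nm] <-
        predict(clf, feats[test_rows, subsets[[nm]], drop = FALSE])
    }
  }

  predictions <- cbind(meta, as.data.frame(preds) |>
                         stats::setNames(paste0("predicted_",
                                                PREDICTION_STREAMS)))
  rows <- actual_row_label(meta$true_label, meta$side, meta$impaired_side)
  confusion <- lapply(PREDICTION_STREAMS, function(s) {
    confusion_from_predictions(rows, preds[, s])
  })
  names(confusion) <- PREDICTION_STREAMS

  res <- structure(list(predictions = predictions, confusion = confusion),
                   class = "loso_result")
  if (vote) {
    res$vote <- lapply(PREDICTION_STREAMS, majority_vote,
                       predictions = predictions)
    names(res$vote) <- PREDICTION_STREAMS
  }
  res
}

#' Majority-voting post-processing of per-passage predictions
#'
#' Each per-passage, per-side prediction casts one vote. Healthy-elderly and
#' Huntington-like subjects pool the votes of both sides into a single
#' subject-level poll; post-stroke subjects get two polls, one per side
#' (impaired / not impaired), since the side distinction is clinically
#' relevant for them. The class with the most votes wins; ties go to the
#' class with the larger vote count over all of that subject's passages, then
#' to the fixed class order EL, PS, HD.
#'
#' @param predictions The `predictions` data frame of a `loso_result` (or any
#'   data frame with columns `subject_id`, `side`, `true_label`,
#'   `impaired_side` and the requested prediction column).
#' @param stream Which prediction stream to vote on (default `"svm_full"`).
#' @return A list: `tallies` (one row per voting unit: vote counts, winner,
#'   true label) and `confusion` (subject-level confusion matrix with
#'   post-stroke subjects split by side).
#' @export
majority_vote <- function(predictions, stream = "svm_full") {
  col <- paste0("predicted_", stream)
  if (!col %in% names(predictions)) {
    stop("no prediction column '", col, "'", call. = FALSE)
  }
  unit_row <- actual_row_label(predictions$true_label, predictions$side,
                               predictions$impaired_side)
  unit_id <- ifelse(predictions$true_label == "PS",
                    paste0(predictions$subject_id, "/", unit_row),
                    predictions$subject_id)
  tallies <- do.call(rbind, lapply(split(seq_len(nrow(predictions)), unit_id),
                                   function(idx) {
    votes <- table(factor(predictions[[col]][idx], levels = GAIT_CLASSES))
    if (sum(votes) == 0L) {
      stop("empty vote set for unit ", unit_id[idx[1]], call. = FALSE)
    }
    top <- GAIT_CLASSES[votes == max(votes)]
    if (length(top) > 1L) {
      # tie: count votes over all passages of the subject (both sides)
      sidx <- predictions$subject_id == predictions$subject_id[idx[1]]
      subj_votes <- table(factor(predictions[[col]][sidx],
                                 levels = GAIT_CLASSES))[top]
      top <- top[subj_votes == max(subj_votes)]
    }
    data.frame(unit = unit_id[idx[1]],
               subject_id = predictions$subject_id[idx[1]],
               actual = unit_row[idx[1]],
               true_label = predictions$true_label[idx[1]],
               n_votes = as.integer(sum(votes)),
               EL = as.integer(votes["EL"]), PS = as.integer(votes["PS"]),
               HD = as.integer(votes["HD"]),
               winner = top[1])   # top is in fixed class order
  }))
  rownames(tallies) <- NULL
  list(tallies = tallies,
       confusion = confusion_from_predictions(tallies$actual, tallies$winner))
}
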