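# RBF-kernel SVM over feature vectors (libSVM via e1071), with a grid search
# that maximizes the *minimum* class-specific accuracy — the selection
# criterion that keeps the smallest class from being sacrificed for overall
# accuracy — scored by subject-grouped inner cross-validation so no subject
# contributes to both sides of a split.

#' SVM training configuration
#'
#' @param C_grid Grid of misclassification-cost values (libSVM `cost`).
#'   Default: the customary coarse exponential grid `2^(-5), 2^(-3), ...,
#'   2^15`.
#' @param gamma_grid Grid of RBF kernel widths. Default `2^(-15), 2^(-13),
#'   ..., 2^3`.
#' @param inner_folds Number of subject-grouped folds used to score each
#'   `(C, gamma)` pair (default 5).
#' @param normalization `"zscore"` (default; per-feature standardization with
#'   statistics from the training portion only) or `"none"`.
#' @param class_weights `"balanced"` (default) weights each class inversely
#'   to its training count, so the classifier's implicit prior does not track
#'   class imbalance — in particular the imbalance a leave-one-subject-out
#'   fold induces by depleting the held-out subject's class; `"none"` uses
#'   unit weights.
#' @param seed Seed for the fold assignment shuffle.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       inner_folds = 5L,
                       normalization = c("zscore", "none"),
                       class_weights = c("balanced", "none"),
                       seed = 0L) {
  normalization <- match.arg(normalization)
  class_weights <- match.arg(class_weights)
  if (length(C_grid) == 0L || length(gamma_grid) == 0L) {
    stop("C and gamma grids must be nonempty", call. = FALSE)
  }
  if (any(C_grid <= 0) || any(gamma_grid <= 0)) {
    stop("C and gamma must be positive", call. = FALSE)
  }
  if (inner_folds < 2L) stop("inner_folds must be >= 2", call. = FALSE)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 inner_folds = as.integer(inner_folds),
                 normalization = normalization,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "svm_config")
}

# Subject-grouped, class-stratified fold assignment: named integer vector
# subject -> fold.
grouped_folds <- function(subjects, labels, k, seed) {
  subj_lab <- tapply(labels, subjects, function(x) x[1])
  with_fixed_seed(seed, {
    folds <- integer(0)
    for (cls in unique(subj_lab)) {
      ids <- sample(names(subj_lab)[subj_lab == cls])
      folds[ids] <- rep(seq_len(k), length.out = length(ids))
    }
    folds
  })
}

# Per-class misclassification-cost multipliers: inverse training frequency
# (normalized to mean 1), or unit weights.
balance_weights <- function(y, config) {
  counts <- table(y)
  if (identical(config$class_weights, "none")) {
    w <- rep(1, length(counts))
  } else {
    w <- sum(counts) / (length(counts) * as.numeric(counts))
  }
  stats::setNames(w, names(counts))
}

zscore_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_zscore <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean), 2, stats$sd, `/`)
}

#' Train an RBF SVM with min-class-accuracy grid search
#'
#' For every `(C, gamma)` pair the classifier is scored by subject-grouped
#' inner k-fold cross-validation; the pair maximizing the minimum
#' class-specific accuracy is selected (ties: smaller C, then smaller gamma)
#' and the model refitted on all training data. Feature normalization
#' statistics are computed on the training data only and stored with the
#' classifier.
#'
#' @param features Numeric matrix, one row per trial-side.
#' @param labels Class labels (`EL`, `PS`, `HD`), one per row.
#' @param subjects Subject identifier per row, used to group the inner folds.
#' @param config An [svm_config()].
#' @return An object of class `gait_svm` holding the fitted libSVM model, the
#'   chosen `(C, gamma)`, the normalization statistics and the grid of
#'   min-class-accuracy scores.
#' @export
grid_search_train <- function(features, labels, subjects,
                              config = svm_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  subjects <- as.character(subjects)
  present <- unique(labels)
  missing <- setdiff(GAIT_CLASSES, present)
  if (length(missing) > 0L) {
    stop("class absent from training data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_subj <- tapply(subjects, labels, function(s) length(unique(s)))
  if (any(n_subj < 2L)) {
    stop("need >= 2 subjects per class for grouped model selection; class ",
         names(n_subj)[which.min(n_subj)], " has ", min(n_subj), call. = FALSE)
  }
  k <- min(config$inner_folds, max(n_subj))
  fold_of <- grouped_folds(subjects, labels, k, config$seed)
  row_fold <- fold_of[subjects]

  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), ]
  y <- factor(labels, levels = GAIT_CLASSES)

  # one pass over folds, scoring every grid pair on the same splits
  correct <- matrix(0, nrow(grid), length(GAIT_CLASSES))
  total <- stats::setNames(numeric(3), GAIT_CLASSES)
  for (f in seq_len(k)) {
    test <- row_fold == f
    if (!any(test) || length(unique(labels[!test])) < 3L) next
    total <- total + tabulate(y[test], 3)
    Xtr <- features[!test, , drop = FALSE]
    Xte <- features[test, , drop = FALSE]
    if (config$normalization == "zscore") {
      st <- zscore_stats(Xtr)
      Xtr <- apply_zscore(Xtr, st)
      Xte <- apply_zscore(Xte, st)
    }
    ytr <- y[!test]
    wtr <- balance_weights(ytr, config)
    for (g in seq_len(nrow(grid))) {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = FALSE,
                        class.weights = wtr)
      pred <- predict(fit, Xte)
      ok <- pred == y[test]
      for (cls in seq_along(GAIT_CLASSES)) {
        correct[g, cls] <- correct[g, cls] +
          sum(ok[y[test] == GAIT_CLASSES[cls]])
      }
    }
  }
  class_acc <- sweep(correct, 2, total, `/`)
  scores <- apply(class_acc, 1, min)
  best <- which.max(scores)          # grid is sorted by (C, gamma): first max

  stats <- if (config$normalization == "zscore") zscore_stats(features)
           else list(mean = rep(0, ncol(features)),
                     sd = rep(1, ncol(features)))
  Xn <- apply_zscore(features, stats)
  fit <- e1071::svm(Xn, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE,
                    class.weights = balance_weights(y, config))
  structure(list(model = fit, C = grid$C[best], gamma = grid$gamma[best],
                 normalization = stats, config = config,
                 grid_scores = cbind(grid, min_class_accuracy = scores)),
            class = "gait_svm")
}

#' Predict gait classes for feature vectors
#'
#' @param object A `gait_svm` from [grid_search_train()].
#' @param newdata Numeric matrix (rows = trial-sides) or a single feature
#'   vector.
#' @param ... Unused.
#' @return Character vector of class labels.
#' @export
predict.gait_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (anyNA(newdata) || any(!is.finite(newdata))) {
    stop("non-finite feature values", call. = FALSE)
  }
  Xn <- apply_zscore(newdata, object$normalization)
  as.character(predict(object$model, Xn))
}
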