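#' Classification metrics from a pooled confusion matrix
#'
#' Accuracy is the trace over the total; precision and recall are macro
#' averages of the per-class values (a class never predicted contributes 0
#' to macro precision, with a warning); F1 is the harmonic mean of macro
#' precision and macro recall. All reported in percent. Rows of the
#' confusion matrix are the true classes, columns the predictions.
#'
#' @param confusion Square non-negative count matrix with a positive total.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(confusion)) / total
  prec_den <- colSums(confusion)
  rec_den <- rowSums(confusion)
  if (any(prec_den == 0))
    warning("class never predicted; its precision contributes 0")
  prec <- ifelse(prec_den > 0, diag(confusion) / prec_den, 0)
  rec <- ifelse(rec_den > 0, diag(confusion) / rec_den, 0)
  mp <- mean(prec)
  mr <- mean(rec)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(accuracy = 100 * acc, precision = 100 * mp, recall = 100 * mr,
       f1 = 100 * f1)
}

# stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt round-robin, so fold class proportions differ from the
# global ones by at most one subject
make_folds <- function(labels, k_folds, seed) {
  folds <- integer(length(labels))
  withr_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  folds
}

#' Cross-validated evaluation of one classifier on a feature table
#'
#' Stratified k-fold cross-validation: folds are drawn from the seed;
#' within each fold the feature columns are z-scored with mean and sd
#' fitted on the training rows only; predictions are pooled over folds into
#' a single confusion matrix from which the metrics are computed. The
#' whole evaluation is deterministic given the seed.
#'
#' If the smallest class has fewer subjects than `k_folds`, the fold count
#' is reduced to that size with a warning.
#'
#' @param table A `feature_table` (all rows are used; restrict to UWS/MCS
#'   beforehand for the binary task, see [subset_task()]).
#' @param spec A [classifier_spec()].
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and bootstrap resampling.
#' @return An object of class `eval_report`: metrics (percent), pooled
#'   confusion matrix, per-subject fold assignment, seed, number of
#'   features.
#' @export
run_cv <- function(table, spec, k_folds = 10, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            inherits(spec, "classifier_spec"))
  if (any(!is.finite(table$values))) stop("feature table contains NaN")
  classes <- intersect(c("coma", "UWS", "MCS"), unique(table$labels))
  if (length(classes) == 0) classes <- sort(unique(table$labels))
  if (length(classes) < 2) stop("need at least 2 classes to classify")
  y <- factor(table$labels, levels = classes)
  smallest <- min(table(y))
  if (smallest < k_folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    k_folds, smallest))
    k_folds <- smallest
  }
  folds <- make_folds(as.character(y), k_folds, seed)
  x <- table$values
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, pred = classes))
  preds <- character(length(y))
  withr_seed(seed + 1L, {
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      mu <- colMeans(x[tr, , drop = FALSE])
      sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      pred <- fit_and_predict(spec, xtr, y[tr], xte)
      preds[!tr] <- as.character(pred)
      for (i in which(!tr))
        confusion[as.character(y[i]), preds[i]] <-
          confusion[as.character(y[i]), preds[i]] + 1L
    }
  })
  metrics <- classification_metrics(confusion)
  structure(
    list(classifier = spec$kind, metrics = metrics, confusion = confusion,
         folds = folds, predictions = preds, seed = seed,
         n_features = ncol(x), k_folds = k_folds),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "%s (%d-fold CV, %d features): acc %.1f%%, prec %.1f%%, rec %.1f%%, F1 %.1f%%\n",
    x$classifier, x$k_folds, x$n_features, x$metrics$accuracy,
    x$metrics$precision, x$metrics$recall, x$metrics$f1))
  invisible(x)
}

#' Restrict a feature table to the subjects of one classification task
#'
#' The binary task keeps the UWS and MCS subjects; the multiclass task
#' keeps all labeled subjects.
#'
#' @param table A `feature_table`.
#' @param task `"multiclass"` or `"binary"`.
#' @return The restricted `feature_table`.
#' @export
subset_task <- function(table, task = c("multiclass", "binary")) {
  task <- match.arg(task)
  keep <- if (task == "binary") table$labels %in% c("UWS", "MCS")
          else !is.na(table$labels)
  table$values <- table$values[keep, , drop = FALSE]
  table$labels <- table$labels[keep]
  table$subject_ids <- table$subject_ids[keep]
  table$crs_r <- table$crs_r[keep]
  table$gcs <- table$gcs[keep]
  table
}

#' Relative accuracy improvement, in percent of the reference
#'
#' `(new - ref) / ref * 100`, rounded to one decimal for report tables.
#'
#' @param new_acc,ref_acc Accuracies in percent; `ref_acc` must be > 0.
#' @return Relative improvement in percent (1 decimal).
#' @export
relative_improvement <- function(new_acc, ref_acc) {
  if (any(ref_acc <= 0)) stop("reference accuracy must be positive")
  round((new_acc - ref_acc) / ref_acc * 100, 1)
}

#' Absolute accuracy improvement, in percentage points
#'
#' `sel_acc - all_acc`; may be negative when selection hurts.
#'
#' @param sel_acc,all_acc Accuracies in percent.
#' @return Difference in percentage points (1 decimal).
#' @export
absolute_improvement <- function(sel_acc, all_acc) {
  round(sel_acc - all_acc, 1)
}
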