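#' Configuration of a full classification experiment
#'
#' Bundles everything [run_experiment()] needs: a cohort source (a
#' [cohort_spec()] or a directory of CSV recordings), the representations
#' and tasks to evaluate, the feature / decomposition / selection /
#' cross-validation settings, and the output directory.
#'
#' @param cohort A [cohort_spec()] (synthetic cohort) or a directory path
#'   for [read_recordings()].
#' @param approaches Subset of `c("raw", "bands", "vmd")`.
#' @param tasks Subset of `c("binary", "multiclass")`.
#' @param classifiers Character vector of classifier kinds (see
#'   [classifier_spec()]).
#' @param fspec A [feature_spec()].
#' @param vmd_cfg A [vmd_config()].
#' @param bands Band table as from [eeg_bands()].
#' @param broadband Broadband band-pass edges in Hz applied during
#'   preprocessing.
#' @param alpha Kruskal-Wallis selection level.
#' @param folds Cross-validation folds.
#' @param seed Master seed for cohort generation and evaluation.
#' @param selection_in_folds If `TRUE`, re-run the feature screen inside
#'   every training fold (leak-free variant) instead of once on the full
#'   table (the default, which mirrors the original protocol).
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              approaches = c("raw", "bands", "vmd"),
                              tasks = c("binary", "multiclass"),
                              classifiers = c("knn", "linear_svm",
                                              "decision_tree",
                                              "ensemble_bagged_tree"),
                              fspec = feature_spec(), vmd_cfg = vmd_config(),
                              bands = eeg_bands(), broadband = c(0.1, 45),
                              alpha = 0.05, folds = 10, seed = 1L,
                              selection_in_folds = FALSE,
                              output_dir = NULL) {
  stopifnot(length(approaches) >= 1, length(tasks) >= 1,
            length(classifiers) >= 1)
  approaches <- match.arg(approaches, c("raw", "bands", "vmd"),
                          several.ok = TRUE)
  tasks <- match.arg(tasks, c("binary", "multiclass"), several.ok = TRUE)
  structure(
    list(cohort = cohort, approaches = approaches, tasks = tasks,
         classifiers = classifiers, fspec = fspec, vmd_cfg = vmd_cfg,
         bands = bands, broadband = broadband, alpha = alpha,
         folds = folds, seed = as.integer(seed),
         selection_in_folds = isTRUE(selection_in_folds),
         output_dir = output_dir),
    class = "experiment_config"
  )
}

# 32-bit polynomial rolling hash of the serialized config, for tagging
# outputs (doubles hold the 2^32 modulus exactly). The output path is not
# part of the scientific configuration and is excluded.
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "output_dir")]
  s <- utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                       collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full classification experiment
#'
#' Orchestrates the pipeline: obtain the cohort (generate or read),
#' preprocess every recording (average reference, broadband band-pass,
#' 17-channel subset), extract features under each requested
#' representation, screen features per task with the Kruskal-Wallis test,
#' and evaluate every classifier on both the full and the selected feature
#' sets under stratified cross-validation. Comparison tables (relative
#' improvement of the VMD representation over bands/raw, and the absolute
#' selection gain) are derived from the accuracy table.
#'
#' @param config An [experiment_config()].
#' @return A list with `results` (data frame: task, approach, feature_set,
#'   classifier, n_features, accuracy, precision, recall, f1), `reports`
#'   (nested list of `eval_report`s), `selections` (per task x approach),
#'   `comparisons` (improvement tables), `config_hash` and `seed`;
#'   written to `output_dir` as CSV plus a JSON summary when requested.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  seed <- config$seed

  stage_log("cohort", "seed %d", seed)
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    spc <- config$cohort
    spc$seed <- seed
    generate_cohort(spc)
  } else {
    read_recordings(config$cohort)
  }
  stage_log("cohort", "%d recordings, %d channels, %.0f s",
            length(cohort), nrow(cohort[[1]]$data),
            ncol(cohort[[1]]$data) / cohort[[1]]$fs)

  stage_log("preprocess", "average reference + band-pass %.1f-%.1f Hz",
            config$broadband[1], config$broadband[2])
  cohort <- lapply(cohort, preprocess_recording,
                   broadband = config$broadband)

  tables <- list()
  for (ap in config$approaches) {
    stage_log("features", "approach %s", ap)
    tables[[ap]] <- extract_features(cohort, ap, config$fspec,
                                     config$vmd_cfg, config$bands)
  }

  results <- list()
  reports <- list()
  selections <- list()
  for (task in config$tasks) {
    for (ap in config$approaches) {
      tab <- subset_task(tables[[ap]], task)
      sel <- select_features(tables[[ap]], config$alpha, task)
      selections[[task]][[ap]] <- sel
      stage_log("select", "%s/%s: %d of %d features at p < %g",
                task, ap, length(sel$selected), ncol(tab$values),
                config$alpha)
      for (fset in c("all", "selected")) {
        use_tab <- if (fset == "all") tab else {
          if (length(sel$selected) == 0) next
          subset_features(tab, sel$selected)
        }
        for (clf in config$classifiers) {
          rep_ <- run_cv(use_tab, classifier_spec(clf, random_seed = seed),
                         k_folds = config$folds, seed = seed)
          reports[[task]][[ap]][[fset]][[clf]] <- rep_
          results[[length(results) + 1L]] <- data.frame(
            task = task, approach = ap, feature_set = fset,
            classifier = clf, n_features = rep_$n_features,
            accuracy = rep_$metrics$accuracy,
            precision = rep_$metrics$precision,
            recall = rep_$metrics$recall, f1 = rep_$metrics$f1,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, results)
  comparisons <- comparison_tables(results)

  out <- list(results = results, reports = reports,
              selections = selections, comparisons = comparisons,
              config_hash = hash, seed = seed)
  if (!is.null(config$output_dir)) write_experiment(out, config)
  out
}

#' Improvement tables from an experiment accuracy table
#'
#' From a results data frame (columns `task`, `approach`, `feature_set`,
#' `classifier`, `accuracy`) derives:
#' \describe{
#'   \item{relative}{per task x classifier x feature set, the relative
#'     accuracy improvement (percent) of the VMD representation over the
#'     band and raw representations;}
#'   \item{absolute}{per task x approach x classifier, the accuracy gain
#'     (percentage points) of the selected over the full feature set.}
#' }
#'
#' @param results Data frame as produced by [run_experiment()], or any
#'   table with the five columns above (e.g. transcribed reference
#'   results).
#' @return List with data frames `relative` and `absolute`.
#' @export
comparison_tables <- function(results) {
  need <- c("task", "approach", "feature_set", "classifier", "accuracy")
  stopifnot(all(need %in% names(results)))
  acc <- function(task, ap, fset, clf) {
    v <- results$accuracy[results$task == task & results$approach == ap &
                            results$feature_set == fset &
                            results$classifier == clf]
    if (length(v) == 1) v else NA_real_
  }
  rel <- list()
  for (task in unique(results$task))
    for (fset in unique(results$feature_set))
      for (clf in unique(results$classifier)) {
        v <- acc(task, "vmd", fset, clf)
        vb <- acc(task, "bands", fset, clf)
        vr <- acc(task, "raw", fset, clf)
        if (is.na(v)) next
        rel[[length(rel) + 1L]] <- data.frame(
          task = task, feature_set = fset, classifier = clf,
          vmd_over_bands = if (is.na(vb)) NA_real_ else
            relative_improvement(v, vb),
          vmd_over_raw = if (is.na(vr)) NA_real_ else
            relative_improvement(v, vr),
          stringsAsFactors = FALSE)
      }
  abs_ <- list()
  for (task in unique(results$task))
    for (ap in unique(results$approach))
      for (clf in unique(results$classifier)) {
        a_all <- acc(task, ap, "all", clf)
        a_sel <- acc(task, ap, "selected", clf)
        if (is.na(a_all) || is.na(a_sel)) next
        abs_[[length(abs_) + 1L]] <- data.frame(
          task = task, approach = ap, classifier = clf,
          acc_all = a_all, acc_selected = a_sel,
          improvement = absolute_improvement(a_sel, a_all),
          stringsAsFactors = FALSE)
      }
  list(relative = if (length(rel)) do.call(rbind, rel) else NULL,
       absolute = if (length(abs_)) do.call(rbind, abs_) else NULL)
}

write_experiment <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$output_dir, f)
  utils::write.csv(cbind(out$results, config_hash = out$config_hash),
                   pth("results.csv"), row.names = FALSE)
  if (!is.null(out$comparisons$relative))
    utils::write.csv(cbind(out$comparisons$relative,
                           config_hash = out$config_hash),
                     pth("improvement_relative.csv"), row.names = FALSE)
  if (!is.null(out$comparisons$absolute))
    utils::write.csv(cbind(out$comparisons$absolute,
                           config_hash = out$config_hash),
                     pth("improvement_absolute.csv"), row.names = FALSE)
  summary <- list(config_hash = out$config_hash, seed = out$seed,
                  results = out$results,
                  relative = out$comparisons$relative,
                  absolute = out$comparisons$absolute)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Write a cohort as per-subject CSV files plus a manifest
#'
#' Each recording becomes `<subject_id>.csv` (rows = samples, header =
#' channel names); `manifest.csv` lists subject_id, file, fs, label, crs_r,
#' gcs.
#'
#' @param cohort List of [recording()] objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(cohort, function(rec) {
    f <- paste0(rec$subject_id, ".csv")
    df <- as.data.frame(t(rec$data))
    colnames(df) <- rec$channel_names
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    data.frame(subject_id = rec$subject_id, file = f, fs = rec$fs,
               label = rec$label, crs_r = rec$crs_r, gcs = rec$gcs,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort of CSV recordings
#'
#' Expects the layout written by [write_recordings()]: a `manifest.csv`
#' with columns `subject_id`, `file`, `fs`, `label`, `crs_r`, `gcs`, and
#' one CSV per subject (rows = samples, header = channel names). Channels
#' are validated against the montage: extra channels are dropped with a
#' warning, missing channels are an error naming them, and labels outside
#' coma/UWS/MCS are rejected.
#'
#' @param dir Directory containing `manifest.csv`.
#' @param channels Required channel set (default [doc_channels()]).
#' @return List of [recording()] objects.
#' @export
read_recordings <- function(dir, channels = doc_channels()) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "fs", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (!row$label %in% c("coma", "UWS", "MCS"))
      stop("invalid label '", row$label, "' for subject ", row$subject_id)
    df <- utils::read.csv(file.path(dir, row$file), check.names = FALSE)
    missing <- setdiff(channels, names(df))
    if (length(missing))
      stop("subject ", row$subject_id, " is missing channels: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(names(df), channels)
    if (length(extra))
      warning("subject ", row$subject_id, ": dropping extra channels ",
              paste(extra, collapse = ", "))
    data <- t(as.matrix(df[, channels, drop = FALSE]))
    recording(data, fs = row$fs, channel_names = channels,
              subject_id = row$subject_id, label = row$label,
              crs_r = if ("crs_r" %in% names(row)) row$crs_r else NA,
              gcs = if ("gcs" %in% names(row)) row$gcs else NA)
  })
}

#' Reference accuracy tables from the original clinical evaluation
#'
#' Accuracies (percent) reported in the clinical study whose protocol this
#' package re-implements, transcribed as a data frame with columns `task`,
#' `approach`, `feature_set`, `classifier`, `accuracy`. These values are
#' shipped only so the improvement arithmetic of [comparison_tables()] can
#' be verified against the published comparison figures; they are never
#' produced by, nor compared against, this package's own pipeline runs.
#'
#' @return Data frame of published accuracies.
#' @export
reference_accuracies <- function() {
  path <- system.file("extdata", "reference_accuracies.csv",
                      package = "vmdeeg")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
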