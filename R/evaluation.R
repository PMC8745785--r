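# Evaluation: confusion-matrix metrics with A (apnea) as the positive
# class, spectrogram-level stratified k-fold cross-validation,
# leave-one-subject-out cross-validation, and REM/non-REM stratified
# evaluation with optional random undersampling of the majority class.

#' Confusion matrix for apnea-vs-normal predictions
#'
#' @param truth,pred Factors or character vectors over `{N, A}`; `A` is the
#'   condition-positive class.
#' @param tp,fp,fn,tn Alternatively, the four counts directly.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(truth = NULL, pred = NULL, tp = NULL, fp = NULL,
                             fn = NULL, tn = NULL) {
  if (is.null(tp)) {
    truth <- factor(as.character(truth), levels = CLASS_LEVELS)
    pred <- factor(as.character(pred), levels = CLASS_LEVELS)
    stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
    tp <- sum(truth == "A" & pred == "A")
    fp <- sum(truth == "N" & pred == "A")
    fn <- sum(truth == "A" & pred == "N")
    tn <- sum(truth == "N" & pred == "N")
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy = (TP + TN) / (P + N), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), with P = TP + FN and N = FP + TN.
#' A ratio with zero denominator (a fold without positives or without
#' negatives) is reported as `NaN` with a warning, never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (fractions in \[0, 1\]).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm$tp + cm$fn
  n <- cm$fp + cm$tn
  if (p + n == 0) stopf("all-zero confusion matrix")
  sens <- if (p == 0) {
    warnf("no condition-positive samples: sensitivity undefined (NaN)")
    NaN
  } else cm$tp / p
  spec <- if (n == 0) {
    warnf("no condition-negative samples: specificity undefined (NaN)")
    NaN
  } else cm$tn / n
  c(accuracy = (cm$tp + cm$tn) / (p + n), sensitivity = sens, specificity = spec)
}

eval_report <- function(scheme, per_fold, config_fingerprint, extra = list()) {
  agg <- colMeans(per_fold[, c("accuracy", "sensitivity", "specificity"),
                           drop = FALSE], na.rm = TRUE)
  n_def <- colSums(!is.na(per_fold[, c("accuracy", "sensitivity", "specificity"),
                                   drop = FALSE]))
  pooled <- confusion_matrix(tp = sum(per_fold$tp), fp = sum(per_fold$fp),
                             fn = sum(per_fold$fn), tn = sum(per_fold$tn))
  structure(
    c(list(scheme = scheme, per_fold = per_fold, aggregate = agg,
           metric_fold_counts = n_def,
           pooled = suppressWarnings(metrics(pooled)),
           config_fingerprint = config_fingerprint),
      extra),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s> %d fold(s)\n", x$scheme, nrow(x$per_fold)))
  cat(sprintf("  mean accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              x$aggregate["accuracy"], x$aggregate["sensitivity"],
              x$aggregate["specificity"]))
  invisible(x)
}

fold_row <- function(fold_id, truth, pred) {
  cm <- confusion_matrix(truth, pred)
  met <- suppressWarnings(metrics(cm))
  data.frame(fold = fold_id, n = length(truth),
             tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
             accuracy = met[["accuracy"]] * 100,
             sensitivity = met[["sensitivity"]] * 100,
             specificity = met[["specificity"]] * 100,
             stringsAsFactors = FALSE)
}

#' Spectrogram-level stratified k-fold cross-validation
#'
#' Folds are drawn over individual windows/spectrograms, not subjects: one
#' subject's windows may land in both training and test folds. That is the
#' record-level protocol most apnea-ECG studies report; contrast with
#' [losocv()], which keeps subjects intact. Folds are stratified so each
#' keeps the class mix. The aggregate is the unweighted mean of per-fold
#' metrics (a pooled-confusion variant is also included in the report).
#'
#' @param features A `bof_features` object.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold shuffling.
#' @return An `eval_report` (scheme `"kfold"`); metrics in percent.
#' @export
kfold_cv <- function(features, spec, k = 5, seed = 1) {
  features <- as_bof_features(features)
  y <- features$label
  if (nlevels(droplevels(y)) < 2) stopf("both classes must be present")
  fold <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- subset_features(features, fold != f)
    te <- subset_features(features, fold == f)
    model <- train_classifier(tr, spec)
    fold_row(f, te$label, predict(model, te))
  })
  eval_report("kfold", do.call(rbind, rows),
              fingerprint(list("kfold", spec, k, seed)),
              extra = list(k = k, seed = seed, stratified = TRUE))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the model never sees any window of the held-out
#' subject during training, exposing how much record-level k-fold accuracy
#' comes from the model memorizing subjects rather than the condition.
#' Subjects whose windows are single-class are still evaluated; their
#' undefined metric is `NaN` and is excluded from that metric's mean (the
#' per-metric fold counts are reported, and `aggregate_nan_as_zero` gives
#' the variant that counts undefined entries as zero).
#'
#' @param features A `bof_features` object with `record_id` set.
#' @param spec A [classifier_spec()].
#' @return An `eval_report` (scheme `"losocv"`); metrics in percent.
#' @export
losocv <- function(features, spec) {
  features <- as_bof_features(features)
  subjects <- unique(features$record_id)
  if (length(subjects) < 2) stopf("leave-one-subject-out needs >= 2 subjects")
  rows <- lapply(subjects, function(s) {
    tr <- subset_features(features, features$record_id != s)
    te <- subset_features(features, features$record_id == s)
    if (nlevels(droplevels(tr$label)) < 2) {
      stopf("training split for held-out subject '%s' is single-class", s)
    }
    model <- train_classifier(tr, spec)
    r <- fold_row(s, te$label, predict(model, te))
    r
  })
  per_fold <- do.call(rbind, rows)
  pf0 <- per_fold
  pf0[is.na(pf0)] <- 0
  eval_report("losocv", per_fold, fingerprint(list("losocv", spec)),
              extra = list(
                subjects = subjects,
                aggregate_nan_as_zero = colMeans(
                  pf0[, c("accuracy", "sensitivity", "specificity")])
              ))
}

#' REM / non-REM stratified evaluation
#'
#' Runs an independent stratified k-fold evaluation within each sleep-stage
#' stratum. Because splitting by stage typically unbalances apnea vs normal
#' counts, the majority class can be randomly undersampled to the minority
#' count first (seeded, reproducible).
#'
#' @param features A `bof_features` object whose `stage` entries are
#'   `"REM"`/`"NREM"` (windows with unknown stage are refused).
#' @param spec A [classifier_spec()].
#' @param balance `"none"` or `"random_undersample"`.
#' @param seed Integer seed for undersampling and fold shuffling.
#' @param k Folds within each stratum (default 5).
#' @return Named list of two `eval_report`s: `REM` and `NREM`.
#' @export
stage_stratified_eval <- function(features, spec,
                                  balance = c("none", "random_undersample"),
                                  seed = 1, k = 5) {
  balance <- match.arg(balance)
  features <- as_bof_features(features)
  if (all(features$stage == "UNKNOWN")) {
    stopf("no sleep-stage labels present; stage-stratified evaluation cannot run")
  }
  out <- lapply(c(REM = "REM", NREM = "NREM"), function(st) {
    idx <- which(features$stage == st)
    if (length(idx) == 0) stopf("no windows in stage %s", st)
    sub <- subset_features(features, idx)
    if (nlevels(droplevels(sub$label)) < 2) {
      stopf("stage %s stratum is single-class", st)
    }
    if (balance == "random_undersample") {
      sub <- undersample_majority(sub, seed)
    }
    kfold_cv(sub, spec, k = k, seed = seed)
  })
  out
}

# seeded random undersampling of the majority class to the minority count;
# a no-op when classes are already balanced
undersample_majority <- function(features, seed) {
  tab <- table(features$label)
  if (tab["N"] == tab["A"]) return(features)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(CLASS_LEVELS, minority)
  maj_idx <- which(features$label == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, min(tab))))
  subset_features(features, sort(c(which(features$label == minority), keep_maj)))
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Destination file; the JSON is stable for identical
#'   corpus/spec/seed inputs.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
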