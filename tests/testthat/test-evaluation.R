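test_that("metrics reproduce the confusion-matrix formulas", {
  m <- metrics(confusion_matrix(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(unname(m["sensitivity"]), 0.90)
  expect_equal(unname(m["specificity"]), 0.80)
  expect_equal(unname(m["accuracy"]), 0.85)
  perfect <- metrics(confusion_matrix(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("zero-denominator metrics are NaN with a warning, never silent zeros", {
  expect_warning(m <- metrics(confusion_matrix(tp = 0, fn = 0, tn = 8, fp = 2)),
                 "sensitivity undefined")
  expect_true(is.nan(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 0.8)
  expect_warning(m2 <- metrics(confusion_matrix(tp = 3, fn = 1, tn = 0, fp = 0)),
                 "specificity undefined")
  expect_true(is.nan(m2["specificity"]))
  expect_error(metrics(confusion_matrix(tp = 0, fn = 0, tn = 0, fp = 0)),
               "all-zero")
})

test_that("accuracy equals the sensitivity/specificity mixture identity", {
  set.seed(41)
  for (i in 1:200) {
    cm <- confusion_matrix(tp = rpois(1, 20) + 1, fp = rpois(1, 10),
                           fn = rpois(1, 5) + 1, tn = rpois(1, 30))
    m <- metrics(cm)
    p <- cm$tp + cm$fn
    n <- cm$fp + cm$tn
    expect_equal(unname(m["accuracy"]),
                 unname((m["sensitivity"] * p + m["specificity"] * n) / (p + n)),
                 tolerance = 1e-12)
  }
})

test_that("confusion_matrix counts labels with A as the positive class", {
  truth <- c("A", "A", "N", "N", "A", "N")
  pred <- c("A", "N", "N", "A", "A", "N")
  cm <- confusion_matrix(truth, pred)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2L, 1L, 1L, 2L))
})

test_that("k-fold test folds partition the data with stratified sizes", {
  feats <- separable_features(n_per_class = 50)
  rep5 <- kfold_cv(feats, classifier_spec("svm"), k = 5, seed = 1)
  expect_identical(rep5$per_fold$n, rep(20L, 5)) # 100 samples, 5 folds of 20
  expect_identical(sum(rep5$per_fold$tp + rep5$per_fold$fp +
                         rep5$per_fold$fn + rep5$per_fold$tn), 100L)
  expect_equal(unname(rep5$aggregate["accuracy"]), 100)
  expect_equal(unname(rep5$aggregate["accuracy"]),
               mean(rep5$per_fold$accuracy), tolerance = 1e-9)
  expect_error(kfold_cv(feats, classifier_spec("svm"), k = 200), "folds")
})

test_that("LOSOCV makes one fold per subject and refuses a single subject", {
  feats <- small_features()
  rep_l <- losocv(feats, classifier_spec("knn", k = 3))
  expect_identical(sort(rep_l$per_fold$fold), sort(unique(feats$record_id)))
  expect_equal(nrow(rep_l$per_fold), 2)
  solo <- subset_one <- bof_features(feats$X, feats$label,
                                     record_id = rep("only", nrow(feats$X)))
  expect_error(losocv(solo, classifier_spec("knn")), ">= 2 subjects")
})

test_that("single-class subjects get NaN metrics excluded from that average", {
  set.seed(42)
  X <- matrix(rnorm(90 * 4), 90, 4)
  X[1:45, 1] <- X[1:45, 1] + 4
  lab <- rep(c("A", "N"), c(45, 45))
  rid <- c(rep("s1", 25), rep("s2", 40), rep("s3", 25)) # s1 all-A, s3 all-N
  feats <- bof_features(X, lab, record_id = rid)
  rep_l <- losocv(feats, classifier_spec("knn", k = 3))
  s1 <- rep_l$per_fold[rep_l$per_fold$fold == "s1", ]
  expect_true(is.nan(s1$specificity)) # no negatives for an all-apnea subject
  expect_equal(unname(rep_l$metric_fold_counts["specificity"]), 2)
  expect_false(anyNA(rep_l$aggregate))
  expect_true(all(is.finite(rep_l$aggregate_nan_as_zero)))
})

test_that("stage-stratified evaluation balances classes reproducibly", {
  base <- small_features()
  # assign stages deterministically so both strata hold both classes
  feats <- bof_features(base$X, base$label, record_id = base$record_id,
                        stage = rep(c("REM", "NREM"), length.out = nrow(base$X)))
  spec <- classifier_spec("knn", k = 3)
  reps <- stage_stratified_eval(feats, spec, balance = "random_undersample",
                                seed = 5)
  expect_named(reps, c("REM", "NREM"))
  for (st in c("REM", "NREM")) {
    tot <- sum(reps[[st]]$per_fold$n)
    in_stage <- table(feats$label[feats$stage == st])
    expect_identical(tot, as.integer(2 * min(in_stage))) # balanced count
  }
  reps2 <- stage_stratified_eval(feats, spec, balance = "random_undersample",
                                 seed = 5)
  expect_identical(reps$REM$per_fold, reps2$REM$per_fold)
  # balanced input makes undersampling a no-op
  bal <- apneabof:::undersample_majority(separable_features(), seed = 1)
  expect_identical(nrow(bal$X), nrow(separable_features()$X))
  # stage labels are required
  nostage <- bof_features(feats$X, feats$label)
  expect_error(stage_stratified_eval(nostage, spec), "stage")
})

test_that("reports serialize deterministically for identical inputs", {
  feats <- separable_features(n_per_class = 25)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.json"); p2 <- file.path(dir, "r2.json")
  write_eval_report(kfold_cv(feats, classifier_spec("svm", seed = 3),
                             k = 5, seed = 3), p1)
  write_eval_report(kfold_cv(feats, classifier_spec("svm", seed = 3),
                             k = 5, seed = 3), p2)
  expect_identical(readLines(p1), readLines(p2))
})
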