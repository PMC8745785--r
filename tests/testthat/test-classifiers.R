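test_that("linearly separable clusters are fit perfectly by the SVM", {
  feats <- separable_features()
  model <- train_classifier(feats, classifier_spec("svm"))
  expect_identical(as.character(predict(model, feats)),
                   as.character(feats$label))
})

test_that("1-NN reproduces training labels on the training set", {
  feats <- separable_features(gap = 1) # overlapping is fine for 1-NN
  model <- train_classifier(feats, classifier_spec("knn", k = 1))
  expect_identical(as.character(predict(model, feats)),
                   as.character(feats$label))
})

test_that("seeded ensembles are deterministic on a held-out probe set", {
  feats <- separable_features(gap = 2)
  probe <- separable_features(n_per_class = 15, gap = 2, seed = 99)
  for (family in c("el_bagged_trees", "el_subspace_knn")) {
    m1 <- train_classifier(feats, classifier_spec(family, seed = 7))
    m2 <- train_classifier(feats, classifier_spec(family, seed = 7))
    expect_identical(predict(m1, probe), predict(m2, probe))
    expect_identical(m1$training_fingerprint, m2$training_fingerprint)
  }
})

test_that("degenerate inputs are refused and empty prediction lists pass through", {
  feats <- separable_features()
  one_class <- bof_features(feats$X[feats$label == "N", ],
                            rep("N", sum(feats$label == "N")))
  expect_error(train_classifier(one_class, classifier_spec("svm")),
               "2 examples per class")
  model <- train_classifier(feats, classifier_spec("knn"))
  expect_length(predict(model, bof_features(feats$X[0, , drop = FALSE],
                                            character(0))), 0)
  wrong_dim <- bof_features(feats$X[, 1:3], feats$label)
  expect_error(predict(model, wrong_dim), "dimension")
  expect_error(classifier_spec("svm", bogus = 1), "unknown hyperparameter")
})

test_that("KNN matches an exhaustive-distance oracle for both metrics", {
  set.seed(31)
  n_tr <- 300; n_te <- 150; d <- 12
  Xtr <- matrix(runif(n_tr * d), n_tr, d)
  ytr <- ifelse(rowSums(Xtr[, 1:3]) > 1.5, "A", "N")
  Xte <- matrix(runif(n_te * d), n_te, d)
  tr <- bof_features(Xtr, ytr)
  for (metric in c("euclidean", "cosine")) {
    for (k in c(1, 5)) {
      model <- train_classifier(tr, classifier_spec("knn", k = k, metric = metric))
      pred <- predict(model, bof_features(Xte, rep("N", n_te)))
      oracle <- character(n_te)
      for (i in seq_len(n_te)) {
        dists <- numeric(n_tr)
        for (j in seq_len(n_tr)) {
          dists[j] <- if (metric == "euclidean") {
            sum((Xte[i, ] - Xtr[j, ])^2)
          } else {
            1 - sum(Xte[i, ] * Xtr[j, ]) /
              (sqrt(sum(Xte[i, ]^2)) * sqrt(sum(Xtr[j, ]^2)))
          }
        }
        nn <- order(dists)[seq_len(k)]
        votes <- table(factor(ytr[nn], levels = c("N", "A")))
        oracle[i] <- names(votes)[which.max(votes)]
      }
      expect_identical(as.character(pred), oracle)
    }
  }
})

test_that("subspace-KNN predictions equal a brute-force recount of learner votes", {
  set.seed(32)
  Xtr <- matrix(runif(200 * 10), 200, 10)
  ytr <- ifelse(Xtr[, 1] + Xtr[, 2] > 1, "A", "N")
  Xte <- matrix(runif(80 * 10), 80, 10)
  tr <- bof_features(Xtr, ytr)
  model <- train_classifier(tr, classifier_spec("el_subspace_knn", seed = 3))
  pred <- predict(model, bof_features(Xte, rep("N", 80)))
  expect_length(model$fit$subspaces, 30) # 30 learners
  votes <- matrix("", 80, 30)
  for (b in seq_len(30)) {
    dims <- model$fit$subspaces[[b]]
    for (i in seq_len(80)) {
      d2 <- colSums((t(Xtr[, dims, drop = FALSE]) - Xte[i, dims])^2)
      votes[i, b] <- ytr[which.min(d2)]
    }
  }
  recount <- apply(votes, 1, function(v) {
    tb <- table(factor(v, levels = c("N", "A")))
    c("N", "A")[which.max(tb)]
  })
  expect_identical(as.character(pred), recount)
})

test_that("a singleton grid reduces nested CV to plain stratified k-fold", {
  feats <- small_features()
  res <- grid_search_nested(feats, "knn", list(k = 5), outer_k = 5,
                            inner_k = 3, seed = 2)
  expect_equal(nrow(res$per_fold), 5)
  plain <- kfold_cv(feats, classifier_spec("knn", k = 5, seed = 2), k = 5,
                    seed = 2)
  expect_equal(res$per_fold$accuracy, plain$per_fold$accuracy)
  expect_equal(unname(res$aggregate["accuracy"]),
               unname(plain$aggregate["accuracy"]))
  # determinism of the whole nested report
  res2 <- grid_search_nested(feats, "knn", list(k = 5), outer_k = 5,
                             inner_k = 3, seed = 2)
  expect_identical(res$per_fold, res2$per_fold)
})

test_that("nested CV picks the inner-accuracy argmax and keeps folds leak-free", {
  # overlapping classes: candidates genuinely differ in inner-CV accuracy
  set.seed(33)
  n <- 120
  X <- rbind(matrix(rnorm(n * 4), ncol = 4),
             matrix(rnorm(n * 4, mean = 0.9), ncol = 4))
  feats <- bof_features(X, rep(c("N", "A"), each = n))
  grid <- list(cost = c(1, 10000), gamma = c(5))
  res <- grid_search_nested(feats, "svm", grid, outer_k = 5, inner_k = 5,
                            seed = 6)
  # independent re-derivation of each outer fold's inner scores
  outer_fold <- apneabof:::stratified_folds(feats$label, 5, seed = 6)
  cand <- expand.grid(grid)
  for (f in 1:5) {
    tr <- apneabof:::subset_features(feats, outer_fold != f)
    inner <- vapply(seq_len(nrow(cand)), function(ci) {
      sp <- classifier_spec("svm", cost = cand$cost[ci], gamma = cand$gamma[ci],
                            seed = 6)
      unname(kfold_cv(tr, sp, k = 5, seed = 6 + f)$aggregate["accuracy"])
    }, numeric(1))
    best <- which.max(inner)
    expect_equal(res$per_fold$cost[f], cand$cost[best])
    expect_equal(res$per_fold$inner_accuracy[f], max(inner))
    # no leakage: the outer test fold never enters the inner loop's data
    expect_length(intersect(which(outer_fold != f), which(outer_fold == f)), 0)
  }
})
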