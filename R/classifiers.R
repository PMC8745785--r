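# Classifier families over BoF histograms: RBF support vector machine,
# k-nearest neighbours (Euclidean or cosine distance), and two ensembles —
# bagged decision trees and a random-subspace KNN majority vote of 30
# learners. The SVM fit is delegated to e1071 (libsvm) and single trees to
# rpart; the KNN rule, bagging loop and subspace ensemble are implemented
# here so predictions are exactly the documented deterministic rules.

CLASS_LEVELS <- c("N", "A") # N = negative (normal), A = positive (apnea)

#' Classifier specification
#'
#' @param family One of `"svm"` (RBF kernel), `"knn"`,
#'   `"el_bagged_trees"`, `"el_subspace_knn"`.
#' @param ... Family-specific hyperparameters:
#'   \describe{
#'     \item{svm}{`cost` (default 1), `gamma` (default `"auto"` =
#'       1/dimension, or numeric kernel scale)}
#'     \item{knn}{`k` (default 5), `metric` (`"euclidean"` or `"cosine"`)}
#'     \item{el_bagged_trees}{`n_trees` (default 30), `sample_fraction`
#'       (default 1; bootstrap resample size as a fraction of n)}
#'     \item{el_subspace_knn}{`n_learners` (default 30), `k` (default 1),
#'       `subspace_dim` (default `ceiling(d / 2)`)}
#'   }
#' @param seed Integer seed controlling every stochastic step of the fit.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "el_bagged_trees",
                                       "el_subspace_knn"),
                            ..., seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(cost = 1, gamma = "auto"),
    knn = list(k = 5, metric = "euclidean"),
    el_bagged_trees = list(n_trees = 30, sample_fraction = 1),
    el_subspace_knn = list(n_learners = 30, k = 1, subspace_dim = NULL)
  )
  user <- list(...)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stopf("unknown hyperparameter(s) for %s: %s", family,
                         paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, user)
  if (family == "knn" || family == "el_subspace_knn") stopifnot(is_count(hp$k))
  if (family == "knn") hp$metric <- match.arg(hp$metric, c("euclidean", "cosine"))
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

features_xy <- function(features) {
  if (inherits(features, "bof_features")) {
    list(X = features$X, y = factor(features$label, levels = CLASS_LEVELS))
  } else if (is.list(features) && all(vapply(features, inherits, TRUE, "bof_vector"))) {
    list(
      X = do.call(rbind, lapply(features, `[[`, "freqs")),
      y = factor(vapply(features, `[[`, "", "label"), levels = CLASS_LEVELS)
    )
  } else {
    stopf("features must be a bof_features object or a list of bof_vector")
  }
}

knn_dist <- function(train, test, metric) {
  if (metric == "cosine") {
    nt <- sqrt(rowSums(train^2)); nt[nt == 0] <- 1
    ns <- sqrt(rowSums(test^2)); ns[ns == 0] <- 1
    1 - (test / ns) %*% t(train / nt)
  } else {
    matrix(rowSums(test^2), nrow(test), nrow(train)) -
      2 * test %*% t(train) +
      matrix(rowSums(train^2), nrow(test), nrow(train), byrow = TRUE)
  }
}

# majority vote among the k nearest training points; distance ties are
# resolved by training-set order, vote ties by class order (N before A)
knn_predict_matrix <- function(D, train_y, k) {
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    votes <- table(factor(train_y[nn], levels = CLASS_LEVELS))
    CLASS_LEVELS[which.max(votes)]
  })
}

#' Train a classifier on BoF features
#'
#' @param features A `bof_features` object (or list of `bof_vector`) with
#'   labels over `{N, A}`; both classes must be represented by at least two
#'   examples.
#' @param spec A [classifier_spec()].
#' @return An object of class `apnea_model` carrying the fitted state, the
#'   spec, the class order (`N` negative, `A` positive) and a fingerprint of
#'   the training features. Refitting with the same data and seed gives
#'   identical predictions.
#' @export
train_classifier <- function(features, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  xy <- features_xy(features)
  X <- xy$X; y <- xy$y
  if (anyNA(y)) stopf("training labels must be N or A")
  tab <- table(y)
  if (any(tab < 2)) {
    stopf("need >= 2 examples per class; got N=%d, A=%d", tab["N"], tab["A"])
  }
  hp <- spec$hyperparams
  fit <- switch(spec$family,
    svm = {
      # "auto" kernel scale: 1 / (d * mean feature variance), so the RBF
      # width tracks the spread of the (small-valued) histogram features
      gamma <- if (identical(hp$gamma, "auto")) {
        v <- mean(apply(X, 2, stats::var))
        if (v <= 0) 1 / ncol(X) else 1 / (ncol(X) * v)
      } else hp$gamma
      with_seed(spec$seed,
        e1071::svm(x = X, y = y, kernel = "radial", cost = hp$cost,
                   gamma = gamma, scale = FALSE)
      )
    },
    knn = list(X = X, y = y),
    el_bagged_trees = with_seed(spec$seed, {
      n <- nrow(X)
      m <- max(2L, round(hp$sample_fraction * n))
      df <- data.frame(y = y, X)
      lapply(seq_len(hp$n_trees), function(b) {
        idx <- sample.int(n, m, replace = TRUE)
        while (length(unique(df$y[idx])) < 2) idx <- sample.int(n, m, replace = TRUE)
        rpart::rpart(y ~ ., data = df[idx, , drop = FALSE], method = "class",
                     control = rpart::rpart.control(xval = 0, cp = 0.01))
      })
    }),
    el_subspace_knn = with_seed(spec$seed, {
      d <- ncol(X)
      sd_ <- hp$subspace_dim %||% ceiling(d / 2)
      subspaces <- lapply(seq_len(hp$n_learners), function(b) sort(sample.int(d, sd_)))
      list(X = X, y = y, subspaces = subspaces)
    })
  )
  structure(
    list(spec = spec, fit = fit, classes = CLASS_LEVELS, dim = ncol(X),
         training_fingerprint = fingerprint(list(X, as.character(y), spec))),
    class = "apnea_model"
  )
}

#' @export
print.apnea_model <- function(x, ...) {
  cat(sprintf("<apnea_model> %s (d = %d), fingerprint %s\n",
              x$spec$family, x$dim, substr(x$training_fingerprint, 1, 8)))
  invisible(x)
}

#' Predict apnea/normal labels
#'
#' @param object An `apnea_model`.
#' @param features A `bof_features` object (or list of `bof_vector`).
#' @param ... Unused.
#' @return A factor over `{N, A}`, one label per input row, in input order.
#' @export
predict.apnea_model <- function(object, features, ...) {
  xy <- features_xy(features)
  X <- xy$X
  if (nrow(X) == 0) return(factor(character(0), levels = CLASS_LEVELS))
  if (ncol(X) != object$dim) {
    stopf("feature dimension %d does not match training dimension %d",
          ncol(X), object$dim)
  }
  hp <- object$spec$hyperparams
  out <- switch(object$spec$family,
    svm = as.character(stats::predict(object$fit, X)),
    knn = {
      D <- knn_dist(object$fit$X, X, hp$metric)
      knn_predict_matrix(D, object$fit$y, hp$k)
    },
    el_bagged_trees = {
      df <- data.frame(X)
      names(df) <- paste0("X", seq_len(ncol(X)))
      votes <- sapply(object$fit, function(tr)
        as.character(stats::predict(tr, df, type = "class")))
      votes <- matrix(votes, nrow = nrow(X))
      apply(votes, 1, function(v) {
        tb <- table(factor(v, levels = CLASS_LEVELS))
        CLASS_LEVELS[which.max(tb)]
      })
    },
    el_subspace_knn = {
      votes <- sapply(object$fit$subspaces, function(dims) {
        D <- knn_dist(object$fit$X[, dims, drop = FALSE],
                      X[, dims, drop = FALSE], "euclidean")
        knn_predict_matrix(D, object$fit$y, hp$k)
      })
      votes <- matrix(votes, nrow = nrow(X))
      apply(votes, 1, function(v) {
        tb <- table(factor(v, levels = CLASS_LEVELS))
        CLASS_LEVELS[which.max(tb)]
      })
    }
  )
  factor(out, levels = CLASS_LEVELS)
}

#' Nested cross-validated grid search
#'
#' Hyperparameters are selected by an inner stratified k-fold loop run on
#' each outer-fold training set only; the winning candidate is refit on the
#' full outer training set and scored once on the held-out outer fold, so
#' the reported outer metrics are unbiased by the selection.
#'
#' @param features A `bof_features` object.
#' @param family Classifier family (see [classifier_spec()]).
#' @param grid Named list of hyperparameter value vectors, expanded to a
#'   full factorial candidate set. Ties in inner accuracy go to the earlier
#'   candidate in expansion order.
#' @param outer_k,inner_k Fold counts (default 5 and 5).
#' @param seed Integer seed for fold shuffling and model fits.
#' @return A list: `per_fold` data frame (fold, chosen hyperparameters,
#'   confusion counts, accuracy/sensitivity/specificity in percent),
#'   `aggregate` (mean over outer folds), `candidates`, `scheme`.
#' @export
grid_search_nested <- function(features, family, grid, outer_k = 5,
                               inner_k = 5, seed = 1) {
  xy <- features_xy(features)
  candidates <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
                else data.frame(row.names = 1)
  outer_fold <- stratified_folds(xy$y, outer_k, seed)
  rows <- list()
  for (f in seq_len(outer_k)) {
    tr_idx <- which(outer_fold != f)
    te_idx <- which(outer_fold == f)
    tr <- subset_features(as_bof_features(features), tr_idx)
    inner_scores <- vapply(seq_len(nrow(candidates)), function(ci) {
      sp <- do.call(classifier_spec,
                    c(list(family = family), as.list(candidates[ci, , drop = FALSE]),
                      list(seed = seed)))
      rep_in <- kfold_cv(tr, sp, k = inner_k, seed = seed + f)
      rep_in$aggregate["accuracy"]
    }, numeric(1))
    best <- which.max(inner_scores)
    sp <- do.call(classifier_spec,
                  c(list(family = family), as.list(candidates[best, , drop = FALSE]),
                    list(seed = seed)))
    model <- train_classifier(tr, sp)
    pred <- predict(model, subset_features(as_bof_features(features), te_idx))
    cm <- confusion_matrix(xy$y[te_idx], pred)
    met <- suppressWarnings(metrics(cm))
    rows[[f]] <- cbind(
      data.frame(fold = f, inner_accuracy = inner_scores[best]),
      candidates[best, , drop = FALSE],
      data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                 accuracy = met["accuracy"] * 100,
                 sensitivity = met["sensitivity"] * 100,
                 specificity = met["specificity"] * 100)
    )
  }
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  agg <- colMeans(per_fold[, c("accuracy", "sensitivity", "specificity")],
                  na.rm = TRUE)
  list(scheme = "nested_kfold", per_fold = per_fold, aggregate = agg,
       candidates = candidates, seed = seed)
}

as_bof_features <- function(features) {
  if (inherits(features, "bof_features")) return(features)
  xy <- features_xy(features)
  bof_features(xy$X, as.character(xy$y))
}
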