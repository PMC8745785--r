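# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, restoring the caller's state after.
#'
#' All stochastic steps in the package (simulation, k-means++ seeding,
#' fold shuffling, bootstrap resampling) run through this so that a seed in a
#' config reproduces results bitwise without clobbering the user's RNG.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stratified fold assignment: shuffles within each class so every fold keeps
#' the class mix, then deals indices round-robin. Errors if a class has fewer
#' members than folds (that fold would lose the class).
#' @noRd
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k > n) stopf("cannot make %d folds from %d samples", k, n)
  tab <- table(labels)
  if (any(tab < k)) {
    stopf(
      "stratification error: class '%s' has %d sample(s), fewer than k = %d folds",
      names(tab)[which.min(tab)], min(tab), k
    )
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Short stable fingerprint of an arbitrary R object.
#' @noRd
fingerprint <- function(x) rlang::hash(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}
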