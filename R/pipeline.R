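# End-to-end experiment orchestration: ingest -> preprocess -> scalogram ->
# bag-of-features -> classify/evaluate over a band x classifier grid, from a
# single config.

#' Compute spectrogram images for a set of windows
#'
#' Runs the Morlet CWT restricted to `band` on every window and renders the
#' fixed-width grayscale images the visual-features stage consumes.
#'
#' @param windows List of [ecg_window()] (zero-meaned).
#' @param band A [band_spec()] or preset name.
#' @param voices_per_octave,width,compression See [cwt_scalogram()] and
#'   [render_image()].
#' @return List of `spectrogram_image`.
#' @export
featurize_windows <- function(windows, band = "high", voices_per_octave = 12,
                              width = 256, compression = "log1p") {
  band <- as_band_spec(band)
  lapply(windows, function(w) {
    render_image(cwt_scalogram(w, band, voices_per_octave), width = width,
                 compression = compression)
  })
}

#' Experiment configuration
#'
#' @param corpus Either a [sim_config()] (simulated corpus) or a character
#'   vector of CSV record paths.
#' @param window_sec 60 or 10. The low band is refused for 10 s windows:
#'   a 10 s window holds less than one cycle of its sub-0.8 Hz components.
#' @param bands Character vector of band preset names.
#' @param classifiers Named list of [classifier_spec()]s.
#' @param scheme `"kfold"`, `"losocv"`, or `"stage"`.
#' @param k Vocabulary size for the codebook.
#' @param detector Keypoint detector (see [detect_keypoints()]).
#' @param exclude Record ids to drop after ingest (corrupt/duplicate
#'   records).
#' @param artifact_policy An [artifact_policy()], or `NULL` to keep all
#'   windows.
#' @param kfold_k Folds for kfold/stage schemes.
#' @param seed Integer seed for the codebook, folds and classifier fits.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(corpus, window_sec = 60,
                              bands = c("overall", "high", "middle", "low"),
                              classifiers = list(svm = classifier_spec("svm")),
                              scheme = c("kfold", "losocv", "stage"),
                              k = 500, detector = "surf", exclude = character(0),
                              artifact_policy = apneabof::artifact_policy(),
                              kfold_k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(window_sec %in% c(10, 60))
  bands <- match.arg(bands, c("overall", "high", "middle", "low"),
                     several.ok = TRUE)
  if (window_sec == 10 && "low" %in% bands) {
    stopf("the low (0-0.8 Hz) band is not available for 10 s windows")
  }
  if (is.null(names(classifiers)) ||
        !all(vapply(classifiers, inherits, TRUE, "classifier_spec"))) {
    stopf("classifiers must be a named list of classifier_spec")
  }
  structure(
    list(corpus = corpus, window_sec = window_sec, bands = bands,
         classifiers = classifiers, scheme = scheme, k = k,
         detector = detector, exclude = exclude,
         artifact_policy = artifact_policy, kfold_k = kfold_k,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

ingest_corpus <- function(config) {
  records <- if (inherits(config$corpus, "sim_config")) {
    simulate_corpus(config$corpus)$records
  } else if (is.character(config$corpus)) {
    lapply(config$corpus, read_ecg_record, dialect = "csv")
  } else {
    stopf("corpus must be a sim_config or a character vector of CSV paths")
  }
  ids <- vapply(records, `[[`, "", "record_id")
  records[!ids %in% config$exclude]
}

#' Run a full band-by-classifier experiment
#'
#' Executes ingest, preprocessing (zero-mean, windowing, artifact
#' rejection), the wavelet transform per band, codebook construction and
#' encoding, and the configured evaluation scheme for every
#' (band, classifier) cell. A failure in one cell is recorded and does not
#' abort the remaining cells.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_bundle`: `reports` (nested list
#'   `reports[[band]][[classifier]]`), `summary` (data frame with one row
#'   per cell: band, classifier, accuracy/sensitivity/specificity in
#'   percent), `rejected` (artifact audit data frame), `failures`,
#'   `config_fingerprint`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  records <- ingest_corpus(config)
  windows <- unlist(lapply(records, function(r) {
    segment_windows(zero_mean(r), config$window_sec)
  }), recursive = FALSE)
  rejected <- data.frame()
  if (!is.null(config$artifact_policy)) {
    part <- reject_artifacts(windows, config$artifact_policy)
    windows <- part$kept
    rejected <- part$rejected
  }
  reports <- list()
  failures <- list()
  rows <- list()
  for (band in config$bands) {
    cell_images <- tryCatch(
      featurize_windows(windows, band),
      error = function(e) e
    )
    for (cl_name in names(config$classifiers)) {
      cell <- paste(band, cl_name, sep = "/")
      res <- tryCatch({
        if (inherits(cell_images, "error")) stop(cell_images)
        codebook <- build_codebook(cell_images, k = config$k,
                                   seed = config$seed,
                                   detector = config$detector)
        feats <- encode_features(cell_images, codebook,
                                 detector = config$detector)
        spec <- config$classifiers[[cl_name]]
        switch(config$scheme,
          kfold = kfold_cv(feats, spec, k = config$kfold_k, seed = config$seed),
          losocv = losocv(feats, spec),
          stage = stage_stratified_eval(feats, spec,
                                        balance = "random_undersample",
                                        seed = config$seed, k = config$kfold_k)
        )
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[cell]] <- conditionMessage(res)
        next
      }
      reports[[band]][[cl_name]] <- res
      agg <- if (inherits(res, "eval_report")) res$aggregate
             else res$REM$aggregate # stage scheme: summarize the REM report
      rows[[cell]] <- data.frame(
        band = band, classifier = cl_name,
        accuracy = agg[["accuracy"]], sensitivity = agg[["sensitivity"]],
        specificity = agg[["specificity"]]
      )
    }
  }
  structure(
    list(reports = reports,
         summary = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                   else data.frame(),
         rejected = rejected, failures = failures,
         n_windows = length(windows),
         config_fingerprint = fingerprint(config)),
    class = "experiment_bundle"
  )
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d cell(s), %d window(s) kept, %d rejected, fingerprint %s\n",
              nrow(x$summary), x$n_windows, nrow(x$rejected),
              substr(x$config_fingerprint, 1, 8)))
  if (nrow(x$summary)) print(x$summary, digits = 4)
  if (length(x$failures)) {
    cat("failed cells:\n")
    for (nm in names(x$failures)) cat(sprintf("  %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}
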