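# Record containers and readers/writers for annotated single-lead ECG.
#
# Two on-disk dialects are supported:
#   * "wfdb" — a PhysioNet-style header (.hea) + 16-bit signal file (.dat)
#     pair with a binary per-minute apnea annotation stream (.apn);
#   * "csv"  — a two-column `t_sec,mv` table with a sidecar `<record>.labels`
#     file carrying one {N,A[,REM|NREM]} row per minute and an optional
#     `<record>.meta.json` with AHI/age/weight/sex.

#' Subject metadata attached to an ECG record
#'
#' @param ahi Apnea-hypopnea index in events per hour (>= 0), or `NA` when
#'   unknown.
#' @param age Age in years, or `NA`.
#' @param weight Weight in kg, or `NA`.
#' @param sex One of `"F"`, `"M"`, `"unknown"`.
#' @return An object of class `record_meta`.
#' @export
record_meta <- function(ahi = NA_real_, age = NA_real_, weight = NA_real_,
                        sex = "unknown") {
  if (!is.na(ahi) && ahi < 0) stopf("ahi must be >= 0, got %g", ahi)
  sex <- match.arg(sex, c("F", "M", "unknown"))
  structure(
    list(ahi = as.numeric(ahi), age = as.numeric(age),
         weight = as.numeric(weight), sex = sex),
    class = "record_meta"
  )
}

#' A subject's continuous single-lead ECG with per-minute labels
#'
#' The label stream covers the signal minute by minute: label `i` (0-based
#' minute index) covers samples `[i*60*fs, (i+1)*60*fs)`. A trailing partial
#' minute of signal (less than 60 s beyond the labelled span) is permitted.
#'
#' @param record_id Record identifier string.
#' @param samples Numeric vector of voltages (mV); all values must be finite.
#' @param fs Sampling rate in Hz (> 0; clinical corpora use 100 or 200 Hz).
#' @param labels Character vector over `{"N","A"}`, one entry per complete
#'   minute of signal.
#' @param stage_labels Optional character vector over
#'   `{"REM","NREM","UNKNOWN"}` of the same length as `labels`; defaults to
#'   all-`UNKNOWN`.
#' @param meta A [record_meta()] object.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs, labels,
                       stage_labels = NULL, meta = record_meta()) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("fs must be a positive number")
  samples <- as.numeric(samples)
  if (length(samples) == 0) stopf("record '%s' has no samples", record_id)
  if (any(!is.finite(samples))) stopf("record '%s' contains non-finite samples", record_id)
  labels <- as.character(labels)
  if (!all(labels %in% c("N", "A"))) {
    stopf("labels must be 'N' or 'A'; got: %s",
          paste(setdiff(unique(labels), c("N", "A")), collapse = ", "))
  }
  n_min <- length(labels)
  spm <- 60 * fs
  if (length(samples) < n_min * spm || length(samples) >= (n_min + 1) * spm) {
    stopf(
      "record '%s': %d labels do not cover the signal (%d samples at %g Hz = %.2f min)",
      record_id, n_min, length(samples), fs, length(samples) / spm
    )
  }
  if (is.null(stage_labels)) stage_labels <- rep("UNKNOWN", n_min)
  stage_labels <- as.character(stage_labels)
  if (length(stage_labels) != n_min) stopf("stage_labels length must match labels length")
  if (!all(stage_labels %in% c("REM", "NREM", "UNKNOWN"))) {
    stopf("stage labels must be REM, NREM or UNKNOWN")
  }
  if (!inherits(meta, "record_meta")) stopf("meta must be a record_meta object")
  structure(
    list(record_id = as.character(record_id), samples = samples, fs = fs,
         labels = labels, stage_labels = stage_labels, meta = meta),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record '%s'> %d samples @ %g Hz, %d min (%d A / %d N)%s\n",
    x$record_id, length(x$samples), x$fs, length(x$labels),
    sum(x$labels == "A"), sum(x$labels == "N"),
    if (!is.na(x$meta$ahi)) sprintf(", AHI %.1f/h", x$meta$ahi) else ""
  ))
  invisible(x)
}

record_duration_sec <- function(record) length(record$samples) / record$fs

# Align a label stream against the signal: keep one label per complete
# minute, drop a trailing partial minute of signal, and refuse when the label
# stream falls short of the signal by more than one minute.
align_labels <- function(record_id, n_samples, fs, labels, stage_labels = NULL) {
  spm <- 60 * fs
  n_complete <- floor(n_samples / spm)
  if (length(labels) > n_complete) {
    stopf("record '%s': %d labels but only %d complete minutes of signal",
          record_id, length(labels), n_complete)
  }
  deficit_min <- n_samples / spm - length(labels)
  if (deficit_min > 1) {
    stopf(
      "alignment error in record '%s': label stream is %.2f minutes shorter than the signal",
      record_id, deficit_min
    )
  }
  keep <- length(labels) * spm
  list(
    n_keep = keep,
    labels = labels,
    stage_labels = if (!is.null(stage_labels)) stage_labels[seq_along(labels)]
  )
}

#' Read an annotated ECG record
#'
#' @param path For the `wfdb` dialect, the record path without extension (or
#'   the `.hea` file); for the `csv` dialect, the `.csv` file. The sidecar
#'   annotation file (`.apn` / `.labels`) must sit next to the signal file.
#' @param dialect `"wfdb"` or `"csv"`.
#' @return An [ecg_record()].
#' @details Any annotation symbol other than `N` is mapped to `A`: clinical
#'   corpora merge hypopnea and apnea events into one disordered-breathing
#'   class, so every non-normal per-minute symbol counts as apnea. A trailing
#'   partial minute of signal beyond the last label is discarded; a label
#'   stream shorter than the signal by more than one minute is an alignment
#'   error.
#' @export
read_ecg_record <- function(path, dialect = c("wfdb", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_record_csv(path) else read_record_wfdb(path)
}

#' Write an annotated ECG record
#'
#' Inverse of [read_ecg_record()]: emits the signal, the per-minute label
#' sidecar, and (csv dialect) a metadata JSON when any metadata is present.
#'
#' @param record An [ecg_record()].
#' @param path Destination path (without extension for `wfdb`; the `.csv`
#'   file for `csv`).
#' @param dialect `"wfdb"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_ecg_record <- function(record, path, dialect = c("wfdb", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") write_record_csv(record, path) else write_record_wfdb(record, path)
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path)
  if (!all(c("t_sec", "mv") %in% names(tab))) {
    stopf("format error: %s must have columns t_sec,mv", path)
  }
  dt <- diff(tab$t_sec)
  if (length(dt) == 0 || any(dt <= 0)) stopf("format error: non-increasing time axis in %s", path)
  fs <- round(1 / stats::median(dt))
  label_path <- sub("\\.csv$", ".labels", path)
  if (!file.exists(label_path)) stopf("missing sidecar label file: %s", label_path)
  rows <- readLines(label_path)
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(trimws(rows), ",")
  raw <- vapply(parts, `[[`, "", 1)
  labels <- ifelse(raw == "N", "N", "A")
  stages <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "UNKNOWN", "")
  record_id <- sub("\\.csv$", "", basename(path))
  ali <- align_labels(record_id, nrow(tab), fs, labels, stages)
  meta <- record_meta()
  meta_path <- sub("\\.csv$", ".meta.json", path)
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path)
    meta <- record_meta(ahi = m$ahi %||% NA_real_, age = m$age %||% NA_real_,
                        weight = m$weight %||% NA_real_, sex = m$sex %||% "unknown")
  }
  ecg_record(record_id, tab$mv[seq_len(ali$n_keep)], fs, ali$labels,
             stage_labels = ali$stage_labels, meta = meta)
}

write_record_csv <- function(record, path) {
  n <- length(record$samples)
  tab <- data.frame(t_sec = (seq_len(n) - 1) / record$fs, mv = record$samples)
  utils::write.csv(tab, path, row.names = FALSE)
  rows <- ifelse(record$stage_labels == "UNKNOWN", record$labels,
                 paste(record$labels, record$stage_labels, sep = ","))
  writeLines(rows, sub("\\.csv$", ".labels", path))
  m <- record$meta
  if (!is.na(m$ahi) || !is.na(m$age) || !is.na(m$weight) || m$sex != "unknown") {
    keep <- Filter(function(v) !(length(v) == 1 && is.na(v)), unclass(m))
    jsonlite::write_json(keep, sub("\\.csv$", ".meta.json", path), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Group records by metadata rules
#'
#' Builds named dataset groups (severity strata such as "all AHI > 30", the
#' whole corpus, ...) from per-record metadata. A record may belong to
#' several groups.
#'
#' @param metadata A data frame with a `record_id` column plus metadata
#'   columns (`ahi`, `age`, `weight`, `sex`), or a named list of
#'   [record_meta()] objects.
#' @param rules Named list of predicate functions; each receives one metadata
#'   row as a list and returns `TRUE`/`FALSE` (or `NA` when the fields it
#'   needs are missing, which raises an insufficient-metadata error naming
#'   the offending records).
#' @return A list of `dataset_group` objects (fields `name`, `record_ids`,
#'   `criterion`), one per rule, in rule order.
#' @examples
#' md <- data.frame(record_id = c("a01", "a02", "c01"), ahi = c(40, 12, 2))
#' grps <- group_records(md, list(
#'   severe = function(m) m$ahi > 30 & m$ahi <= 45,
#'   all = function(m) TRUE
#' ))
#' grps$severe$record_ids
#' @export
group_records <- function(metadata, rules) {
  if (is.data.frame(metadata)) {
    if (!"record_id" %in% names(metadata)) stopf("metadata needs a record_id column")
    ids <- as.character(metadata$record_id)
    rows <- lapply(seq_len(nrow(metadata)), function(i) as.list(metadata[i, , drop = FALSE]))
  } else {
    ids <- names(metadata)
    if (is.null(ids)) stopf("list metadata must be named by record_id")
    rows <- lapply(metadata, unclass)
  }
  if (anyDuplicated(ids)) stopf("duplicate record ids in metadata")
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) stopf("rules must be a named list")
  out <- lapply(names(rules), function(rule_name) {
    rule <- rules[[rule_name]]
    hits <- vapply(rows, function(r) {
      v <- tryCatch(rule(r), error = function(e) NA)
      if (length(v) != 1 || !is.logical(as.logical(v))) NA else as.logical(v)
    }, logical(1))
    if (anyNA(hits)) {
      stopf("insufficient metadata for rule '%s' on record(s): %s",
            rule_name, paste(ids[is.na(hits)], collapse = ", "))
    }
    desc <- attr(rule, "description") %||% rule_name
    structure(
      list(name = rule_name, record_ids = ids[hits], criterion = desc),
      class = "dataset_group"
    )
  })
  names(out) <- names(rules)
  out
}

#' @export
print.dataset_group <- function(x, ...) {
  cat(sprintf("<dataset_group '%s'> %d record(s) [%s]\n",
              x$name, length(x$record_ids), x$criterion))
  invisible(x)
}
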