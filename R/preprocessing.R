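# Preprocessing: zero-mean the trace, cut it into labelled fixed-length
# windows, and reject artifact-contaminated windows. No filtering or R-peak
# correction is applied: the downstream transform consumes the raw
# zero-meaned trace.

#' Remove the DC offset from a record
#'
#' Subtracts the signal mean so slow electrode drift does not leak into the
#' lowest wavelet scales. All other fields are unchanged.
#'
#' @param record An [ecg_record()].
#' @return The record with zero-mean samples.
#' @export
zero_mean <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) == 0) stopf("empty signal")
  record$samples <- record$samples - mean(record$samples)
  record
}

#' One fixed-length labelled ECG window
#'
#' Windows are the classification unit: each inherits the apnea/normal label
#' (and sleep stage, when known) of the minute it falls in.
#'
#' @param record_id,start_sec,duration_sec,samples,fs,label,stage Fields; see
#'   [segment_windows()].
#' @return An object of class `ecg_window`.
#' @export
ecg_window <- function(record_id, start_sec, duration_sec, samples, fs,
                       label, stage = "UNKNOWN") {
  if (length(samples) != duration_sec * fs) {
    stopf("window needs %g samples, got %d", duration_sec * fs, length(samples))
  }
  structure(
    list(record_id = record_id, start_sec = start_sec,
         duration_sec = duration_sec, samples = as.numeric(samples), fs = fs,
         label = label, stage = stage),
    class = "ecg_window"
  )
}

#' Segment a record into consecutive labelled windows
#'
#' Cuts the zero-meaned signal into consecutive, non-overlapping windows of
#' 60 s (one per annotated minute) or 10 s (six per minute, each inheriting
#' the parent minute's label and stage). Window time intervals are half-open
#' `[start, start + duration)`.
#'
#' @param record A zero-meaned [ecg_record()].
#' @param duration_sec Window length in seconds: 60 or 10.
#' @return A list of [ecg_window()] objects.
#' @export
segment_windows <- function(record, duration_sec = 60) {
  stopifnot(inherits(record, "ecg_record"))
  if (!duration_sec %in% c(10, 60)) {
    stopf("unsupported window duration %g s (use 10 or 60)", duration_sec)
  }
  per_min <- 60 / duration_sec
  spw <- duration_sec * record$fs
  n_min <- length(record$labels)
  out <- vector("list", n_min * per_min)
  w <- 0L
  for (i in seq_len(n_min) - 1L) {
    for (j in seq_len(per_min) - 1L) {
      start_sec <- i * 60 + j * duration_sec
      idx <- start_sec * record$fs + seq_len(spw)
      w <- w + 1L
      out[[w]] <- ecg_window(record$record_id, start_sec, duration_sec,
                             record$samples[idx], record$fs,
                             record$labels[i + 1L], record$stage_labels[i + 1L])
    }
  }
  out
}

#' Artifact-rejection policy
#'
#' Three explicit criteria stand in for the manual removal of contaminated
#' windows: amplitude clipping, flatline runs (sensor detachment), and
#' out-of-band power (a window whose energy is mostly outside the 0.5-40 Hz
#' ECG band is dominated by interference or drift).
#'
#' @param max_abs_mv Reject when any |sample| exceeds this (mV). Default 5.
#' @param max_flatline_sec Reject when the signal stays within
#'   `flatline_tol_mv` of constant for longer than this (s). Default 1.
#' @param min_band_power_ratio Reject when (power in 0.5-40 Hz) / (total
#'   power) falls below this. Default 0.5.
#' @param flatline_tol_mv Sample-to-sample tolerance defining "constant"
#'   (mV). Default 1e-3 (1 microvolt).
#' @return An object of class `artifact_policy`.
#' @export
artifact_policy <- function(max_abs_mv = 5, max_flatline_sec = 1,
                            min_band_power_ratio = 0.5,
                            flatline_tol_mv = 1e-3) {
  stopifnot(max_abs_mv > 0, max_flatline_sec > 0,
            min_band_power_ratio > 0, min_band_power_ratio < 1)
  structure(
    list(max_abs_mv = max_abs_mv, max_flatline_sec = max_flatline_sec,
         min_band_power_ratio = min_band_power_ratio,
         flatline_tol_mv = flatline_tol_mv),
    class = "artifact_policy"
  )
}

longest_flatline_sec <- function(samples, fs, tol) {
  flat <- abs(diff(samples)) < tol
  if (!any(flat)) return(0)
  r <- rle(flat)
  (max(r$lengths[r$values]) + 1) / fs
}

band_power_ratio <- function(samples, fs, f_lo = 0.5, f_hi = 40) {
  n <- length(samples)
  sp <- Mod(stats::fft(samples - mean(samples))[seq_len(floor(n / 2) + 1)])^2
  freqs <- (seq_along(sp) - 1) * fs / n
  tot <- sum(sp[-1]) # DC excluded: the mean is already removed upstream
  if (tot == 0) return(0)
  sum(sp[freqs >= f_lo & freqs <= f_hi]) / tot
}

#' Partition windows into kept and rejected sets
#'
#' Each rejected window carries the first violated criterion, checked in the
#' order clipping, flatline, out-of-band power.
#'
#' @param windows List of [ecg_window()] objects.
#' @param policy An [artifact_policy()].
#' @return A list with elements `kept` (list of windows) and `rejected`
#'   (data frame: `record_id`, `start_sec`, `reason`), together forming a
#'   partition of the input.
#' @export
reject_artifacts <- function(windows, policy = artifact_policy()) {
  stopifnot(inherits(policy, "artifact_policy"))
  if (length(windows) == 0) stopf("windows must be non-empty")
  reason <- vapply(windows, function(w) {
    if (any(abs(w$samples) > policy$max_abs_mv)) return("clipping")
    if (longest_flatline_sec(w$samples, w$fs, policy$flatline_tol_mv) >
          policy$max_flatline_sec) return("flatline")
    if (band_power_ratio(w$samples, w$fs) < policy$min_band_power_ratio) {
      return("band_power")
    }
    ""
  }, character(1))
  bad <- reason != ""
  rejected <- data.frame(
    record_id = vapply(windows[bad], `[[`, "", "record_id"),
    start_sec = vapply(windows[bad], `[[`, 0, "start_sec"),
    reason = reason[bad],
    stringsAsFactors = FALSE
  )
  list(kept = windows[!bad], rejected = rejected)
}
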