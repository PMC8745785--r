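# Minimal WFDB-style record IO: text header (.hea), 16-bit little-endian
# signal file (.dat, format 16), and a binary MIT-format annotation stream
# (.apn) carrying one symbol per minute. Covers the subset of the format the
# apnea corpora use: single signal, format 16, per-minute N/A annotations.

WFDB_CODE_NORMAL <- 1L   # symbol 'N'
WFDB_CODE_APNEA  <- 8L   # symbol 'A'

read_record_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stopf("file not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stopf("format error: garbled header %s", hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stopf("format error: header line needs 'record nsig fs nsamples'")
  record_id <- top[1]
  nsig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(top[3]))
  nsamp <- suppressWarnings(as.numeric(top[4]))
  if (anyNA(c(nsig, fs, nsamp)) || fs <= 0) stopf("format error: garbled header %s", hea)
  if (nsig != 1) stopf("only single-lead records are supported (header declares %d signals)", nsig)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- sig[2]
  if (fmt != "16") stopf("unsupported signal format '%s' (only format 16)", fmt)
  gain <- suppressWarnings(as.numeric(sub("\\(.*$", "", sig[3])))
  if (is.na(gain) || gain <= 0) gain <- 200
  baseline <- 0
  m <- regmatches(sig[3], regexec("\\(([-0-9]+)\\)", sig[3]))[[1]]
  if (length(m) == 2) baseline <- as.numeric(m[2])

  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path)) stopf("file not found: %s", dat_path)
  adc <- readBin(dat_path, "integer", n = nsamp, size = 2, signed = TRUE,
                 endian = "little")
  if (length(adc) < nsamp) {
    stopf("format error: %s holds %d samples, header declares %d",
          dat_path, length(adc), nsamp)
  }
  samples <- (adc - baseline) / gain

  apn <- paste0(base, ".apn")
  if (!file.exists(apn)) stopf("missing apnea annotation stream: %s", apn)
  ann <- read_mit_annotations(apn)
  spm <- 60 * fs
  minute_idx <- round(ann$time / spm)
  labels_by_min <- rep(NA_character_, max(minute_idx) + 1)
  labels_by_min[minute_idx + 1] <- ifelse(ann$code == WFDB_CODE_NORMAL, "N", "A")
  if (anyNA(labels_by_min)) {
    stopf("annotation stream %s skips minute(s): %s", apn,
          paste(which(is.na(labels_by_min)) - 1, collapse = ", "))
  }
  ali <- align_labels(record_id, length(samples), fs, labels_by_min)
  ecg_record(record_id, samples[seq_len(ali$n_keep)], fs, ali$labels)
}

write_record_wfdb <- function(record, path, gain = 200) {
  base <- sub("\\.hea$", "", path)
  record_id <- basename(base)
  n <- length(record$samples)
  writeLines(c(
    sprintf("%s 1 %g %d", record_id, record$fs, n),
    sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 ECG", record_id, gain)
  ), paste0(base, ".hea"))
  adc <- as.integer(round(record$samples * gain))
  if (any(abs(adc) > 32767)) stopf("signal exceeds 16-bit range at gain %g", gain)
  writeBin(adc, paste0(base, ".dat"), size = 2, endian = "little")
  codes <- ifelse(record$labels == "N", WFDB_CODE_NORMAL, WFDB_CODE_APNEA)
  times <- (seq_along(record$labels) - 1) * 60 * record$fs
  write_mit_annotations(paste0(base, ".apn"), times, codes)
  invisible(path)
}

# MIT annotation stream: 16-bit little-endian words; the top 6 bits hold the
# annotation code, the low 10 bits a sample-count increment since the
# previous annotation. Code 59 (SKIP) prefixes a 32-bit increment (high word
# first); a zero word terminates the stream. Codes 60-63 (NUM/SUB/CHN/AUX)
# are modifier records and are skipped on read.
read_mit_annotations <- function(path) {
  raw <- readBin(path, "integer", n = file.size(path) / 2, size = 2,
                 signed = FALSE, endian = "little")
  time <- numeric(0)
  code <- integer(0)
  t <- 0
  i <- 1
  pending_skip <- 0
  while (i <= length(raw)) {
    w <- raw[i]
    cd <- bitwShiftR(w, 10)
    val <- bitwAnd(w, 1023L)
    if (w == 0) break
    if (cd == 59L) {
      if (i + 2 > length(raw)) stopf("truncated SKIP in %s", path)
      hi <- raw[i + 1]
      lo <- raw[i + 2]
      pending_skip <- pending_skip + hi * 65536 + lo
      i <- i + 3
      next
    }
    if (cd >= 60L) { # NUM/SUB/CHN/AUX modifiers
      if (cd == 63L) i <- i + ceiling(val / 2) # aux string payload
      i <- i + 1
      next
    }
    t <- t + val + pending_skip
    pending_skip <- 0
    time <- c(time, t)
    code <- c(code, cd)
    i <- i + 1
  }
  list(time = time, code = code)
}

write_mit_annotations <- function(path, times, codes) {
  stopifnot(length(times) == length(codes), !is.unsorted(times))
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0
  for (j in seq_along(times)) {
    inc <- times[j] - prev
    prev <- times[j]
    if (inc > 1023) {
      writeBin(as.integer(bitwShiftL(59L, 10)), con, size = 2, endian = "little")
      writeBin(as.integer(inc %/% 65536), con, size = 2, endian = "little")
      writeBin(as.integer(inc %% 65536), con, size = 2, endian = "little")
      inc <- 0
    }
    writeBin(as.integer(bitwShiftL(codes[j], 10) + inc), con, size = 2,
             endian = "little")
  }
  writeBin(0L, con, size = 2, endian = "little")
  invisible(path)
}
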