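# Time-frequency transform: Morlet continuous wavelet transform of a window,
# restricted to a named frequency band, rendered as a fixed-width grayscale
# image for the visual-features stage.
#
# The CWT of a window x(t) is X(s, tau) = s^{-1/2} * integral of
# x(t) psi*((t - tau)/s) dt with psi the analytic Morlet wavelet
# exp(i w0 t) exp(-t^2/2), w0 = 6 by convention. It is evaluated in the
# Fourier domain (one FFT of the padded window, one inverse FFT per scale);
# scales map to frequency via f = fc / (s * dt) with fc = w0 / (2 pi).

MORLET_OMEGA0 <- 6

#' Frequency band specification
#'
#' The four preset bands partition the ECG spectrum by physiological origin:
#' `overall` (0.1-50 Hz), `high` (8-50 Hz, QRS energy), `middle`
#' (0.8-10 Hz, dominant heart-rate harmonics), `low` (0-0.8 Hz, baseline and
#' respiration-coupled components). The nominal 0 Hz lower edge of the low
#' band is evaluated from a 0.05 Hz floor, the lowest scale resolvable in a
#' 60 s window.
#'
#' @param name One of `"overall"`, `"high"`, `"middle"`, `"low"`, or
#'   `"custom"` (then `f_lo`/`f_hi` are required).
#' @param f_lo,f_hi Band limits in Hz (custom bands only).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name = c("overall", "high", "middle", "low", "custom"),
                      f_lo = NULL, f_hi = NULL) {
  name <- match.arg(name)
  presets <- list(overall = c(0.1, 50), high = c(8, 50),
                  middle = c(0.8, 10), low = c(0, 0.8))
  if (name != "custom") {
    f_lo <- presets[[name]][1]
    f_hi <- presets[[name]][2]
  }
  if (is.null(f_lo) || is.null(f_hi) || f_lo < 0 || f_lo >= f_hi) {
    stopf("need 0 <= f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

as_band_spec <- function(band) {
  if (inherits(band, "band_spec")) band else band_spec(band)
}

# Log-spaced frequency grid over the band, descending, at the requested
# voices per octave. The low edge is floored at f_floor so the "0 Hz" band
# edge stays finite.
band_freq_grid <- function(band, voices_per_octave = 12, f_floor = 0.05) {
  f_lo <- max(band$f_lo, f_floor)
  n <- ceiling(log2(band$f_hi / f_lo) * voices_per_octave) + 1
  freqs <- band$f_hi * 2^(-(seq_len(n) - 1) / voices_per_octave)
  freqs[freqs >= f_lo - 1e-12]
}

#' Morlet CWT magnitude scalogram of a window
#'
#' @param window A zero-meaned [ecg_window()].
#' @param band A [band_spec()] or preset name; frequencies are evaluated on
#'   a log-spaced grid inside the band.
#' @param voices_per_octave Scales per frequency octave (default 12).
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return An object of class `scalogram`: fields `values` (non-negative
#'   matrix, rows = frequencies descending, cols = time samples), `freqs`
#'   (Hz), `times` (s), `band`, `source_window`.
#' @export
cwt_scalogram <- function(window, band = "overall", voices_per_octave = 12,
                          omega0 = MORLET_OMEGA0) {
  stopifnot(inherits(window, "ecg_window"))
  band <- as_band_spec(band)
  fs <- window$fs
  if (band$f_hi > fs / 2) {
    stopf("band upper edge %g Hz exceeds Nyquist (fs = %g Hz)", band$f_hi, fs)
  }
  x <- window$samples
  n <- length(x)
  dt <- 1 / fs
  freqs <- band_freq_grid(band, voices_per_octave)
  fc <- omega0 / (2 * pi)
  scales <- fc / (freqs * dt) # scale in samples

  npad <- 2^ceiling(log2(2 * n))
  xh <- stats::fft(c(x, rep(0, npad - n)))
  w <- 2 * pi * c(0:(npad / 2), -(npad / 2 - 1):-1) / npad # rad/sample
  vals <- matrix(0, nrow = length(scales), ncol = n)
  pos <- w > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(npad)
    # analytic Morlet in the Fourier domain, unit-energy normalization
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-(s * w[pos] - omega0)^2 / 2)
    wt <- stats::fft(xh * psi_hat, inverse = TRUE) / npad
    vals[j, ] <- Mod(wt[seq_len(n)])
  }
  structure(
    list(values = vals, freqs = freqs, times = (seq_len(n) - 1) * dt,
         band = band,
         source_window = list(record_id = window$record_id,
                              start_sec = window$start_sec,
                              duration_sec = window$duration_sec,
                              label = window$label, stage = window$stage)),
    class = "scalogram"
  )
}

#' Restrict a scalogram to a sub-band
#'
#' Keeps the frequency rows with `f_lo <= f <= f_hi`, preserving order.
#'
#' @param scal A `scalogram`.
#' @param band A [band_spec()] or preset name.
#' @return A `scalogram` over the selected rows.
#' @export
extract_band <- function(scal, band) {
  stopifnot(inherits(scal, "scalogram"))
  band <- as_band_spec(band)
  keep <- scal$freqs >= band$f_lo & scal$freqs <= band$f_hi
  if (!any(keep)) {
    stopf("no scale falls inside %g-%g Hz; recompute with denser scales",
          band$f_lo, band$f_hi)
  }
  scal$values <- scal$values[keep, , drop = FALSE]
  scal$freqs <- scal$freqs[keep]
  scal$band <- band
  scal
}

#' Render a scalogram as a fixed-width grayscale image
#'
#' Magnitudes are compressed (`log1p` by default, matching the dB-like
#' dynamic range of wavelet power), min-max normalized per image to
#' \[0, 255\], and the time axis is linearly resampled to `width` columns.
#' Rows run from high frequency (top) to low. A constant scalogram renders
#' as an all-zero image.
#'
#' @param scal A `scalogram`.
#' @param width Output width in columns (default 256).
#' @param compression `"log1p"` or `"linear"`.
#' @return An object of class `spectrogram_image`: `pixels` (integer matrix
#'   height x width in \[0, 255\]), `height`, `width`, `provenance`.
#' @export
render_image <- function(scal, width = 256, compression = c("log1p", "linear")) {
  stopifnot(inherits(scal, "scalogram"))
  compression <- match.arg(compression)
  v <- scal$values
  if (length(v) == 0) stopf("empty scalogram")
  if (compression == "log1p") v <- log1p(v)
  # resample columns to `width` by linear interpolation along time
  n <- ncol(v)
  if (n != width) {
    at <- seq(1, n, length.out = width)
    lo <- pmin(floor(at), n - 1L)
    fr <- at - lo
    v <- v[, lo, drop = FALSE] * rep(1 - fr, each = nrow(v)) +
      v[, lo + 1L, drop = FALSE] * rep(fr, each = nrow(v))
  }
  # rows descending in frequency (high at top)
  if (is.unsorted(rev(scal$freqs))) v <- v[order(scal$freqs, decreasing = TRUE), , drop = FALSE]
  rng <- range(v)
  # relative tolerance so interpolation round-off on a constant scalogram
  # still renders all-zero
  if (rng[2] - rng[1] < 1e-12 * max(abs(rng), 1)) rng[2] <- rng[1]
  pix <- if (rng[2] > rng[1]) {
    matrix(as.integer(round((v - rng[1]) / (rng[2] - rng[1]) * 255)),
           nrow = nrow(v))
  } else {
    matrix(0L, nrow = nrow(v), ncol = ncol(v))
  }
  structure(
    list(pixels = pix, height = nrow(pix), width = ncol(pix),
         provenance = c(scal$source_window,
                        list(band = scal$band$name, split = "train"))),
    class = "spectrogram_image"
  )
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> %dx%d, band %s, window %s@%gs [%s]\n",
              x$height, x$width, x$provenance$band, x$provenance$record_id,
              x$provenance$start_sec, x$provenance$label))
  invisible(x)
}
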