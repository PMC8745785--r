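# Shared fixtures, built in code and cached per test run so the expensive
# simulation/featurization steps happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a window holding a pure sinusoid (or sum of sinusoids), zero-meaned
sine_window <- function(freqs_hz, duration_sec = 60, fs = 100, amps = 1) {
  t <- (seq_len(duration_sec * fs) - 1) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs_hz,
                      rep_len(amps, length(freqs_hz))))
  ecg_window("tone", 0, duration_sec, x - mean(x), fs, "N")
}

# wrap a raw pixel matrix as a spectrogram image
make_image <- function(pixels, label = "N", record_id = "img", start_sec = 0,
                       split = "train") {
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         provenance = list(record_id = record_id, start_sec = start_sec,
                           duration_sec = 60, label = label,
                           stage = "UNKNOWN", band = "high", split = split)),
    class = "spectrogram_image"
  )
}

# wrap a descriptor matrix as a keypoint set
make_kpset <- function(desc, response = rep(1, nrow(desc)), label = "N",
                       record_id = "img", split = "train") {
  structure(
    list(image_ref = list(record_id = record_id, start_sec = 0,
                          duration_sec = 60, label = label,
                          stage = "UNKNOWN", band = "high", split = split),
         x = rep(1, nrow(desc)), y = rep(1, nrow(desc)),
         scale = rep(2, nrow(desc)), response = response,
         descriptors = desc),
    class = "keypoint_set"
  )
}

# small simulated corpus + high-band features used across modules
small_corpus <- function() {
  cached("small_corpus", simulate_corpus(
    sim_config(n_subjects = 2, minutes_per_subject = 40, seed = 11)
  ))
}

small_features <- function() {
  cached("small_features", {
    corp <- small_corpus()
    wins <- unlist(lapply(corp$records, function(r) {
      segment_windows(zero_mean(r), 60)
    }), recursive = FALSE)
    wins <- reject_artifacts(wins)$kept
    imgs <- featurize_windows(wins, "high")
    cb <- build_codebook(imgs, k = 60, seed = 3)
    encode_features(imgs, cb)
  })
}

# linearly separable two-class feature set
separable_features <- function(n_per_class = 30, d = 8, gap = 4, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  bof_features(X, rep(c("N", "A"), each = n_per_class),
               record_id = rep(c("r1", "r2", "r3"), length.out = 2 * n_per_class))
}
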