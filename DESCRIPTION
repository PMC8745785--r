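Package: apneabof
Title: Sleep Apnea Detection from Single-Lead ECG via Wavelet Scalograms
    and Bag-of-Visual-Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects per-minute sleep apnea events from single-lead nocturnal
    ECG. Windows of the zero-meaned signal are transformed to Morlet
    continuous-wavelet-transform scalograms restricted to physiologically
    motivated frequency bands, rendered as grayscale images, and encoded as
    bag-of-visual-features occurrence histograms over a k-means codebook of
    64-dimensional SURF-style local descriptors. Histograms feed support
    vector machine, k-nearest-neighbour and ensemble classifiers
    (bagged trees, random-subspace KNN), evaluated by spectrogram-level
    stratified k-fold cross-validation, leave-one-subject-out
    cross-validation, and REM/non-REM stratified evaluation. Includes readers
    for WFDB-style and CSV annotated ECG records and a synthetic annotated
    apnea-ECG simulator so the full pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rlang,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
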