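---
title: "Detecting sleep apnea from single-lead ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from single-lead ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneabof)
```

## The problem

Obstructive sleep apnea is conventionally scored from full polysomnography,
which is expensive and poorly tolerated. A long line of work shows that a
single-lead nocturnal ECG carries enough information to flag apneic minutes:
apnea episodes perturb both heart-rate dynamics (cyclic
bradycardia–tachycardia) and beat morphology, and those perturbations are
visible in the time–frequency structure of the raw signal. `apneabof`
implements a window-level classifier built on that observation: each minute
of ECG is turned into a wavelet scalogram image, the image is summarized by
a bag-of-visual-features histogram, and the histogram is classified as
apnea (`A`) or normal (`N`).

The pipeline is, in order:

1. **Ingest** (`read_ecg_record`): WFDB-style or CSV records with one
   `{N, A}` label per minute; any non-`N` annotation symbol is read as `A`,
   because clinical annotation practice merges hypopnea and apnea into one
   disordered-breathing class.
2. **Preprocess** (`zero_mean`, `segment_windows`, `reject_artifacts`):
   subtract the signal mean, cut consecutive non-overlapping 60 s windows
   (or 10 s sub-windows inheriting the parent minute's label), and drop
   artifact-contaminated windows.
3. **Transform** (`cwt_scalogram`, `extract_band`, `render_image`): Morlet
   CWT magnitudes on a log-spaced frequency grid, restricted to one of four
   bands — overall 0.1–50 Hz, high 8–50 Hz, middle 0.8–10 Hz, low
   0–0.8 Hz — and rendered as a fixed-width grayscale image.
4. **Encode** (`detect_keypoints`, `build_codebook`, `encode_features`):
   64-dimensional local descriptors at detected interest points, quantized
   against a k-means codebook of visual words; each image becomes an
   L1-normalized occurrence histogram.
5. **Classify and evaluate** (`classifier_spec`, `kfold_cv`, `losocv`,
   `stage_stratified_eval`, `grid_search_nested`): SVM, KNN, bagged trees
   or random-subspace KNN, under record-level k-fold, subject-held-out, or
   sleep-stage-stratified protocols.

## The wavelet transform

For a window $x(t)$ the continuous wavelet transform is

$$X_w(s, \tau) = \frac{1}{\sqrt{s}} \int_{-\infty}^{\infty} x(t)\,
  \psi^*\!\left(\frac{t - \tau}{s}\right) dt,$$

with $\psi$ the analytic Morlet wavelet
$\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}$ and $s > 0$ a dilation
factor. We evaluate it in the Fourier domain (one FFT of the zero-padded
window, one inverse FFT per scale) and keep magnitudes only. Choices the
wavelet family itself does not pin down:

* **Center frequency** $\omega_0 = 6$, the standard analytic-Morlet
  convention; scales map to frequency as $f = f_c/(s\,\Delta t)$ with
  $f_c = \omega_0 / 2\pi$.
* **Scale grid**: log-spaced at 12 voices per octave spanning each band.
  The low band's nominal 0 Hz edge is floored at 0.05 Hz — the lowest
  frequency that completes three cycles in a 60 s window.
* **Zero padding** to the next power of two at least twice the window
  length, to limit circular wrap-around. Boundary transients still
  dominate the largest scales near the window edges (the cone of
  influence); the property tests that compare band energies therefore
  evaluate interior samples.
* **Rendering**: `log1p` compression (wavelet power is displayed on a
  dB-like range), per-image min–max normalization to $[0, 255]$, time axis
  linearly resampled to 256 columns, rows ordered high-frequency-at-top.
  Per-image normalization makes the encoder sensitive to texture, not to
  absolute signal amplitude. A constant scalogram renders as an all-zero
  image rather than erroring.

The low band is refused for 10 s windows: a sub-0.8 Hz component does not
complete a cycle in 10 s, so the band carries no usable variation at that
window length.

## Bag-of-visual-features

No SURF/OpenCV binding is available in R, so the detector/descriptor pair
is implemented in the package, following the SURF design:

* **Interest points** are local maxima of the scale-normalized determinant
  of Hessian $\sigma^4(L_{xx}L_{yy} - L_{xy}^2)$ at detection scales
  $\sigma \in \{1.6, 2.4, 3.2, 4.8\}$ px, thresholded at $10^{-4}$ on
  unit-range images. A dense-grid variant exists for images too flat for
  blob detection.
* **Descriptors** are upright (rotation-variant) 64-d SURF-style vectors:
  a $16 \times 16$ sample grid around the keypoint, spacing $0.75\sigma$,
  Gaussian-weighted first-order gradients summarized per $4 \times 4$
  subregion as $(\sum d_x, \sum d_y, \sum |d_x|, \sum |d_y|)$,
  L2-normalized. Orientation invariance is deliberately omitted: the
  time/frequency axes of a scalogram have fixed meaning, so rotating
  patches would discard information.
* **Codebook**: k-means (k-means++ seeding, Lloyd iterations capped at
  300) over descriptors pooled from training images only — a provenance
  tag enforces that test-split images can never contribute. Defaults:
  $K = 500$ visual words, the strongest 80% of keypoints by detector
  response, and a 20 000-descriptor cap (seeded subsample) to bound the
  clustering cost. $K$, the retention fraction, and the histogram
  normalization are not dictated by the method's description anywhere we
  know of; these defaults mirror common bag-of-features practice and are
  all configurable.
* **Encoding**: hard assignment to the Euclidean-nearest word (ties to the
  lowest index), L1-normalized counts. An image with no keypoints encodes
  as the uniform histogram $1/K$ and is flagged degenerate.

## Classifiers

SVM fits are delegated to `e1071` (libsvm) with an RBF kernel. The `"auto"`
kernel scale is defined as $\gamma = 1/(d \cdot \overline{\mathrm{Var}}(X))$,
the variance-scaled heuristic: BoF histogram entries are of order $1/K$, and
a plain $1/d$ scale makes all kernel values indistinguishable from 1,
collapsing the fit to the majority class. KNN (Euclidean or cosine,
deterministic tie-breaks: distance ties by training order, vote ties `N`
before `A`), bagged trees (30 `rpart` trees on bootstrap resamples,
majority vote), and random-subspace KNN (30 learners, each a 1-NN on a
random $\lceil d/2 \rceil$-dimensional subspace, majority vote) are
implemented in the package so the prediction rules are exactly the
documented ones. Mahalanobis KNN is omitted by default: histogram features
routinely have singular covariance. The positive class is `A` throughout.

Nested grid search runs an inner stratified k-fold on each outer-fold
training set, picks the inner-accuracy argmax (ties to the earlier grid
point), refits on the outer training set and scores once on the held-out
fold — outer metrics are therefore untouched by the selection.

## Evaluation protocols

`kfold_cv` stratifies folds at the *spectrogram* level: one subject's
windows can appear in both training and test folds. That matches the
protocol most published apnea-ECG results use, and is exactly the setting
`losocv` exists to challenge: with one fold per subject, any accuracy gap
between the two protocols measures how much the model memorizes subjects
rather than the condition. Aggregates are unweighted means over folds;
pooled-confusion variants are also reported. A fold or subject without
positives (or negatives) yields `NaN` sensitivity (specificity) with a
warning; LOSOCV averages exclude undefined entries and report per-metric
fold counts, with an alternative aggregate that counts them as zero — both
conventions appear in the literature, so both are emitted.

`stage_stratified_eval` evaluates REM and NREM windows separately and can
randomly undersample the majority class to the minority count (seeded),
since stage-splitting typically unbalances the classes.

## The simulator

`simulate_corpus` generates annotated corpora so the full pipeline and all
three protocols are exercisable without clinical data. Beats are a
five-lobe Gaussian PQRST template placed at RR intervals; apnea minutes get
(a) a 10 bpm cyclic heart-rate oscillation with a 40 s period, (b) 20%
sinusoidal R-amplitude modulation, and (c) area-preserving QRS blunting —
lobes widened by $(1-\delta)^{-1/2}$ and scaled down by the same factor for
a configured mid-band power drop $\delta = 0.5$ — which reproduces the
direction observed clinically: normal breathing is much stronger than
apnea in the 5–10 Hz band. Defaults: 70 bpm baseline, balanced apnea and
normal minutes (so the chance level of a label-permutation control is
exactly 50%; clinical corpora run nearer 40% apnea at minute level, which
`apnea_minute_fraction` can emulate),
2 subjects × 200 minutes, per-subject log-normal offsets (sd 0.1) on heart
rate, amplitude and QRS width, 2% artifact minutes (flatlines and clipping
bursts, positions recorded in the manifest), and blockwise sleep stages
(90-minute cycles ending in a 20-minute REM bout).

What the simulator does *not* emulate: real HRV spectra, respiratory sinus
arrhythmia physiology, electrode drift, ectopy, or inter-scorer label
noise. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers a planted, physiologically *shaped* contrast — not that
it attains any particular accuracy on clinical recordings.

## Artifact policy

The criteria that define a "contaminated" window are not standardized; the
package uses three explicit, configurable rules — clipping
($|v| > 5$ mV), flatline runs ($> 1$ s within 1 µV), and in-band power
ratio (0.5–40 Hz power below half of total) — applied in that order, with
the first violation recorded per window. This is a declared, reproducible
stand-in for what is usually a manual screening step.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on simulated
corpora sized to exercise every code path at full fidelity while staying
desk-scale: 2 subjects × 200 minutes (seed 7, $K = 200$ words) for the
end-to-end separability, band-relevance and permutation-control checks,
4 subjects × 100 minutes for the subject-effect comparison, and
≤ 500-sample problems for the brute-force classifier oracles. k-means uses
a 20 000-descriptor cap; all stochastic steps (simulation, k-means++
seeding, fold shuffling, bootstrap, undersampling, permutations) are
driven by explicit integer seeds and reruns are bitwise identical.

Known limitations: the WFDB reader covers the single-signal format-16
subset used by the apnea corpora only; no EDF input; no baseline-wander
filtering or R-peak correction (the method deliberately consumes the raw
zero-meaned trace); keypoint detection operates on 8-bit rendered images,
so very low-contrast scalograms can yield few or no keypoints (handled by
the degenerate-histogram fallback).
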