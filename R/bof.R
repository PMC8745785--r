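# Bag-of-visual-features over spectrogram images: interest-point detection,
# 64-dimensional SURF-style upright descriptors, a k-means visual-word
# codebook, and per-image occurrence histograms.
#
# The detector/descriptor pair is implemented here: interest points are
# scale-normalized determinant-of-Hessian maxima (the blob detector SURF
# approximates with box filters), and each point is described by Haar-like
# gradient sums (sum dx, sum dy, sum |dx|, sum |dy|) over a 4x4 subregion
# grid — the classic 64-d upright SURF layout. A dense-grid variant computes
# the same descriptors at fixed locations for images too flat for the blob
# detector.

# -- image-plane helpers ------------------------------------------------------

img_matrix <- function(image) {
  stopifnot(inherits(image, "spectrogram_image"))
  image$pixels / 255
}

# separable Gaussian smoothing with replicated borders
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (o in -r:r) { # rows
    idx <- pmin(pmax(seq_len(h) + o, 1L), h)
    out <- out + k[o + r + 1] * m[idx, , drop = FALSE]
  }
  m2 <- matrix(0, h, w)
  for (o in -r:r) { # cols
    idx <- pmin(pmax(seq_len(w) + o, 1L), w)
    m2 <- m2 + k[o + r + 1] * out[, idx, drop = FALSE]
  }
  m2
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w),
    drop = FALSE]
}

# scale-normalized determinant of Hessian at smoothing scale sigma
hessian_response <- function(m, sigma) {
  L <- gauss_smooth(m, sigma)
  lxx <- shift_mat(L, 0, 1) - 2 * L + shift_mat(L, 0, -1)
  lyy <- shift_mat(L, 1, 0) - 2 * L + shift_mat(L, -1, 0)
  lxy <- (shift_mat(L, 1, 1) + shift_mat(L, -1, -1) -
            shift_mat(L, 1, -1) - shift_mat(L, -1, 1)) / 4
  sigma^4 * (lxx * lyy - lxy^2)
}

local_maxima <- function(resp, threshold, margin = 2L) {
  h <- nrow(resp); w <- ncol(resp)
  if (h < 2 * margin + 1 || w < 2 * margin + 1) return(cbind(row = integer(0), col = integer(0)))
  is_max <- resp > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (resp >= shift_mat(resp, dr, dc))
  }
  is_max[c(seq_len(margin), h - seq_len(margin) + 1L), ] <- FALSE
  is_max[, c(seq_len(margin), w - seq_len(margin) + 1L)] <- FALSE
  which(is_max, arr.ind = TRUE)
}

bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- m[i00];     v01 <- m[i00 + h]
  v10 <- m[i00 + 1]; v11 <- m[i00 + h + 1]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# unit-offset sampling layout shared by all keypoints: a 16x16 sample grid
# (4x4 subregions of 4x4 samples), spacing 0.75 * keypoint scale, with a
# Gaussian weight of sd 3.3 * scale over the patch.
descriptor_layout <- local({
  grid <- seq(-7.5, 7.5, by = 1) * 0.75
  du <- rep(grid, times = 16)
  dv <- rep(grid, each = 16)
  # subregion index: row block from dv, col block from du (4x4 blocks)
  blk <- function(g) pmin(pmax(floor((g / 0.75 + 8) / 4), 0), 3)
  sub <- blk(dv) * 4 + blk(du) + 1
  wgt <- exp(-(du^2 + dv^2) / (2 * 3.3^2))
  ind <- matrix(0, 256, 16)
  ind[cbind(seq_len(256), sub)] <- 1
  list(du = du, dv = dv, wgt = wgt, ind = ind)
})

# 64-d upright SURF-style descriptors for keypoints (x = col, y = row,
# scale in px); vectorized over keypoints. Returns n x 64, rows L2-normalized.
surf_descriptors <- function(m, x, y, scale) {
  n <- length(x)
  if (n == 0) return(matrix(0, 0, 64))
  Ls <- gauss_smooth(m, 1)
  gx <- (shift_mat(Ls, 0, 1) - shift_mat(Ls, 0, -1)) / 2
  gy <- (shift_mat(Ls, 1, 0) - shift_mat(Ls, -1, 0)) / 2
  lay <- descriptor_layout
  X <- outer(x, rep(1, 256)) + outer(scale, lay$du)
  Y <- outer(y, rep(1, 256)) + outer(scale, lay$dv)
  W <- matrix(lay$wgt, n, 256, byrow = TRUE)
  dx <- matrix(bilinear_sample(gx, X, Y), n, 256) * W
  dy <- matrix(bilinear_sample(gy, X, Y), n, 256) * W
  sums <- cbind(dx %*% lay$ind, dy %*% lay$ind,
                abs(dx) %*% lay$ind, abs(dy) %*% lay$ind)
  # interleave to (sum dx, sum dy, sum|dx|, sum|dy|) per subregion
  desc <- sums[, as.vector(rbind(1:16, 17:32, 33:48, 49:64)), drop = FALSE]
  nrm <- sqrt(rowSums(desc^2))
  nrm[nrm == 0] <- 1
  desc / nrm
}

#' Detect keypoints and compute 64-d descriptors on a spectrogram image
#'
#' @param image A [render_image()] output.
#' @param detector `"surf"` — scale-normalized determinant-of-Hessian blob
#'   maxima with upright SURF-style 64-d descriptors (implemented in this
#'   package) — or `"dense"`, the same descriptors on a regular grid.
#' @param threshold Detector response threshold (`surf` only); maxima of the
#'   scale-normalized determinant of Hessian below it are discarded.
#' @param scales Detection scales in pixels.
#' @param grid_step Grid spacing in pixels (`dense` only).
#' @return An object of class `keypoint_set`: `image_ref`, vectors `x`
#'   (column), `y` (row), `scale`, `response`, and `descriptors`
#'   (n x 64 matrix, rows unit length). Deterministic for a fixed image and
#'   configuration; an image without structure yields an empty set.
#' @export
detect_keypoints <- function(image, detector = c("surf", "dense"),
                             threshold = 1e-4,
                             scales = c(1.6, 2.4, 3.2, 4.8),
                             grid_step = 6) {
  detector <- match.arg(detector)
  m <- img_matrix(image)
  if (detector == "surf") {
    xs <- ys <- ss <- rs <- numeric(0)
    for (sg in scales) {
      resp <- hessian_response(m, sg)
      pk <- local_maxima(resp, threshold)
      if (nrow(pk) > 0) {
        xs <- c(xs, pk[, "col"]); ys <- c(ys, pk[, "row"])
        ss <- c(ss, rep(sg, nrow(pk))); rs <- c(rs, resp[pk])
      }
    }
  } else {
    gx_at <- seq(grid_step, ncol(m) - grid_step + 1, by = grid_step)
    gy_at <- seq(2, nrow(m) - 1, by = max(2, grid_step %/% 2))
    pts <- expand.grid(x = gx_at, y = gy_at)
    xs <- rep(pts$x, length(scales))
    ys <- rep(pts$y, length(scales))
    ss <- rep(scales, each = nrow(pts))
    rs <- rep(0, length(xs))
  }
  desc <- surf_descriptors(m, xs, ys, ss)
  if (detector == "dense") {
    rs <- rowSums(desc^2) # response proxy: local gradient energy
    keep <- rs > 0
    xs <- xs[keep]; ys <- ys[keep]; ss <- ss[keep]; rs <- rs[keep]
    desc <- desc[keep, , drop = FALSE]
  }
  structure(
    list(image_ref = image$provenance, x = xs, y = ys, scale = ss,
         response = rs, descriptors = desc),
    class = "keypoint_set"
  )
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints (%s@%gs)\n", length(x$x),
              x$image_ref$record_id %||% "?", x$image_ref$start_sec %||% NA))
  invisible(x)
}

as_keypoint_set <- function(x, ...) {
  if (inherits(x, "keypoint_set")) x else detect_keypoints(x, ...)
}

# seeded k-means++ initial centers
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = probs)
    }
    centers[j + 1, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Build a visual-word codebook by k-means over pooled descriptors
#'
#' Pools descriptors from the training images, optionally keeps only the
#' strongest keypoints by detector response, and clusters them with k-means
#' (k-means++ seeding, Lloyd iterations). Each centroid is one visual word.
#'
#' @param training_images List of `spectrogram_image` or `keypoint_set`
#'   objects. Images tagged with a test split in their provenance are
#'   refused: the codebook may only ever see training data.
#' @param k Vocabulary size (default 500).
#' @param fraction_strongest Fraction of keypoints, ranked by detector
#'   response, kept before clustering (default 0.8).
#' @param seed Integer seed for k-means++ and any subsampling.
#' @param max_descriptors Cap on the pooled descriptor count; a seeded
#'   subsample is clustered beyond it (default 20000).
#' @param ... Passed to [detect_keypoints()] when images are given.
#' @return An object of class `bof_codebook`: `centroids` (k x d), `k`,
#'   `d`, `trained_on` (descriptor count), `seed`.
#' @export
build_codebook <- function(training_images, k = 500, fraction_strongest = 0.8,
                           seed = 1, max_descriptors = 20000, ...) {
  stopifnot(length(training_images) > 0, is_count(k),
            fraction_strongest > 0, fraction_strongest <= 1)
  for (im in training_images) {
    split <- (if (inherits(im, "keypoint_set")) im$image_ref else im$provenance)$split
    if (identical(split, "test")) {
      stopf("leakage guard: image tagged split='test' passed to build_codebook")
    }
  }
  kps <- lapply(training_images, as_keypoint_set, ...)
  desc <- do.call(rbind, lapply(kps, `[[`, "descriptors"))
  resp <- unlist(lapply(kps, `[[`, "response"))
  if (fraction_strongest < 1 && nrow(desc) > 0) {
    n_keep <- max(1L, floor(nrow(desc) * fraction_strongest))
    keep <- order(resp, decreasing = TRUE)[seq_len(n_keep)]
    keep <- sort(keep)
    desc <- desc[keep, , drop = FALSE]
  }
  if (nrow(desc) < k) {
    stopf("only %d descriptors pooled; choose k smaller than that (got k = %d)",
          nrow(desc), k)
  }
  with_seed(seed, {
    if (nrow(desc) > max_descriptors) {
      desc <- desc[sort(sample.int(nrow(desc), max_descriptors)), , drop = FALSE]
    }
    init <- kmeanspp_init(desc, k)
    km <- suppressWarnings(
      stats::kmeans(desc, centers = init, iter.max = 300, algorithm = "Lloyd")
    )
  })
  structure(
    list(centroids = unname(km$centers), k = as.integer(k), d = ncol(desc),
         trained_on = nrow(desc), seed = as.integer(seed)),
    class = "bof_codebook"
  )
}

#' @export
print.bof_codebook <- function(x, ...) {
  cat(sprintf("<bof_codebook> K = %d visual words (d = %d), trained on %d descriptors\n",
              x$k, x$d, x$trained_on))
  invisible(x)
}

nearest_centroid <- function(desc, centroids) {
  # squared Euclidean distance; ties resolved to the lowest centroid index
  d2 <- matrix(rowSums(desc^2), nrow(desc), nrow(centroids)) -
    2 * desc %*% t(centroids) +
    matrix(rowSums(centroids^2), nrow(desc), nrow(centroids), byrow = TRUE)
  max.col(-d2, ties.method = "first")
}

#' Encode an image as a visual-word occurrence histogram
#'
#' Each descriptor is hard-assigned to its Euclidean-nearest visual word
#' (ties to the lowest word index); occurrences are counted and
#' L1-normalized. An image with no keypoints encodes as the uniform
#' histogram `1/K`, flagged as degenerate.
#'
#' @param x A `spectrogram_image` or `keypoint_set`.
#' @param codebook A [build_codebook()] result.
#' @param ... Passed to [detect_keypoints()] when an image is given.
#' @return An object of class `bof_vector`: `freqs` (length-K, sums to 1),
#'   `counts`, `normalized`, `degenerate`, `image_ref`, `label`.
#' @export
encode_bof <- function(x, codebook, ...) {
  stopifnot(inherits(codebook, "bof_codebook"))
  kp <- as_keypoint_set(x, ...)
  if (ncol(kp$descriptors) != codebook$d) {
    stopf("descriptor dimension %d does not match codebook dimension %d",
          ncol(kp$descriptors), codebook$d)
  }
  k <- codebook$k
  if (nrow(kp$descriptors) == 0) {
    freqs <- rep(1 / k, k)
    counts <- rep(0, k)
    degenerate <- TRUE
  } else {
    a <- nearest_centroid(kp$descriptors, codebook$centroids)
    counts <- tabulate(a, nbins = k)
    freqs <- counts / sum(counts)
    degenerate <- FALSE
  }
  structure(
    list(freqs = freqs, counts = counts, normalized = TRUE,
         degenerate = degenerate, image_ref = kp$image_ref,
         label = kp$image_ref$label %||% NA_character_),
    class = "bof_vector"
  )
}

#' Encode a set of images as a feature table for classification
#'
#' @param images List of `spectrogram_image` or `keypoint_set` objects.
#' @param codebook A [build_codebook()] result.
#' @param ... Passed to [encode_bof()].
#' @return An object of class `bof_features`: `X` (n x K matrix of
#'   histograms), `label` (factor with levels N, A), `record_id`, `stage`,
#'   `start_sec`, `degenerate` (logical vector).
#' @export
encode_features <- function(images, codebook, ...) {
  vecs <- lapply(images, encode_bof, codebook = codebook, ...)
  bof_features(
    X = do.call(rbind, lapply(vecs, `[[`, "freqs")),
    label = vapply(vecs, function(v) v$image_ref$label %||% NA_character_, ""),
    record_id = vapply(vecs, function(v) v$image_ref$record_id %||% NA_character_, ""),
    stage = vapply(vecs, function(v) v$image_ref$stage %||% "UNKNOWN", ""),
    start_sec = vapply(vecs, function(v) v$image_ref$start_sec %||% NA_real_, 0),
    degenerate = vapply(vecs, `[[`, TRUE, "degenerate")
  )
}

#' Assemble a feature table from histograms and labels
#'
#' @param X n x K numeric matrix of per-image histograms.
#' @param label Character or factor over `{"N","A"}`.
#' @param record_id,stage,start_sec,degenerate Optional per-row metadata.
#' @return A `bof_features` object.
#' @export
bof_features <- function(X, label, record_id = NULL, stage = NULL,
                         start_sec = NULL, degenerate = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  label <- factor(as.character(label), levels = c("N", "A"))
  stopifnot(length(label) == n, !anyNA(label))
  structure(
    list(X = unname(X), label = label,
         record_id = record_id %||% rep(NA_character_, n),
         stage = stage %||% rep("UNKNOWN", n),
         start_sec = start_sec %||% rep(NA_real_, n),
         degenerate = degenerate %||% rep(FALSE, n)),
    class = "bof_features"
  )
}

subset_features <- function(f, idx) {
  bof_features(f$X[idx, , drop = FALSE], f$label[idx], f$record_id[idx],
               f$stage[idx], f$start_sec[idx], f$degenerate[idx])
}

#' @export
print.bof_features <- function(x, ...) {
  cat(sprintf("<bof_features> %d images x %d words (%d A / %d N, %d subject(s))\n",
              nrow(x$X), ncol(x$X), sum(x$label == "A"), sum(x$label == "N"),
              length(unique(x$record_id))))
  invisible(x)
}

#' Save / load a codebook
#'
#' The centroid matrix is stored as little-endian doubles next to a JSON
#' sidecar carrying the shape, seed and format version.
#'
#' @param codebook A `bof_codebook`.
#' @param path Destination path for the binary centroid file; the sidecar is
#'   written at `<path>.json`.
#' @return `path` (write) or a `bof_codebook` (read).
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "bof_codebook"))
  writeBin(as.vector(t(codebook$centroids)), path, size = 8, endian = "little")
  jsonlite::write_json(
    list(format = "apneabof-codebook", version = 1L, k = codebook$k,
         d = codebook$d, trained_on = codebook$trained_on, seed = codebook$seed),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(meta$format, "apneabof-codebook")) stopf("not a codebook file: %s", path)
  v <- readBin(path, "double", n = meta$k * meta$d, size = 8, endian = "little")
  structure(
    list(centroids = matrix(v, meta$k, meta$d, byrow = TRUE), k = meta$k,
         d = meta$d, trained_on = meta$trained_on, seed = meta$seed),
    class = "bof_codebook"
  )
}
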