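test_that("a structureless image yields no keypoints; detection is deterministic", {
  flat <- make_image(matrix(0L, 32, 256))
  expect_length(detect_keypoints(flat)$x, 0)
  img <- featurize_windows(list(sine_window(c(4, 13))), "middle")[[1]]
  k1 <- detect_keypoints(img)
  k2 <- detect_keypoints(img)
  expect_identical(k1[c("x", "y", "scale", "response", "descriptors")],
                   k2[c("x", "y", "scale", "response", "descriptors")])
  expect_gt(length(k1$x), 0)
  expect_identical(ncol(k1$descriptors), 64L)
  expect_equal(unname(sqrt(rowSums(k1$descriptors^2))),
               rep(1, length(k1$x)), tolerance = 1e-9)
})

test_that("isolated bright blobs are each found inside their bounding box", {
  pix <- matrix(0, 40, 200)
  centers <- cbind(y = c(10, 30, 20, 12, 33), x = c(25, 60, 100, 150, 180))
  for (i in seq_len(nrow(centers))) {
    yy <- outer(seq_len(40) - centers[i, "y"], rep(1, 200))
    xx <- outer(rep(1, 40), seq_len(200) - centers[i, "x"])
    pix <- pix + 255 * exp(-(yy^2 + xx^2) / (2 * 2.5^2))
  }
  kp <- detect_keypoints(make_image(matrix(as.integer(round(pix)), 40, 200)))
  expect_gte(length(kp$x), 5)
  hit <- vapply(seq_len(nrow(centers)), function(i) {
    any(abs(kp$x - centers[i, "x"]) <= 6 & abs(kp$y - centers[i, "y"]) <= 6)
  }, logical(1))
  expect_true(all(hit))
})

test_that("k-means codebook recovers well-separated descriptor clusters", {
  set.seed(8)
  true_centers <- matrix(rnorm(3 * 64), 3, 64) * 3
  desc <- true_centers[rep(1:3, each = 100), ] + matrix(rnorm(300 * 64, sd = 0.05), 300, 64)
  cb <- build_codebook(list(make_kpset(desc)), k = 3, fraction_strongest = 1,
                       seed = 2)
  # match learned centroids to generating centers
  d2 <- as.matrix(dist(rbind(true_centers, cb$centroids)))[1:3, 4:6]
  perm <- unname(apply(d2, 1, which.min))
  expect_identical(sort(perm), 1:3)
  expect_lt(max(d2[cbind(1:3, perm)]), 0.05)
  # assignments are pure
  a <- apneabof:::nearest_centroid(desc, cb$centroids)
  expect_identical(unname(lengths(split(a, rep(1:3, each = 100))) > 0), rep(TRUE, 3))
  expect_true(all(tapply(a, rep(1:3, each = 100), function(v) length(unique(v))) == 1))
})

test_that("k = 1 gives the descriptor mean; same seed reruns are bitwise identical", {
  set.seed(9)
  desc <- matrix(rnorm(50 * 64), 50, 64)
  cb1 <- build_codebook(list(make_kpset(desc)), k = 1, fraction_strongest = 1,
                        seed = 4)
  expect_equal(as.vector(cb1$centroids), colMeans(desc), tolerance = 1e-12)
  # strongest-subset mean when only the top responses are kept
  resp <- seq_len(50)
  cb_half <- build_codebook(list(make_kpset(desc, response = resp)), k = 1,
                            fraction_strongest = 0.5, seed = 4)
  expect_equal(as.vector(cb_half$centroids), colMeans(desc[26:50, ]),
               tolerance = 1e-12)
  cb2 <- build_codebook(list(make_kpset(desc)), k = 1, fraction_strongest = 1,
                        seed = 4)
  expect_identical(cb1$centroids, cb2$centroids)
  expect_error(build_codebook(list(make_kpset(desc)), k = 100),
               "k smaller")
})

test_that("encoding matches an exhaustive nearest-centroid oracle and sums to 1", {
  set.seed(10)
  k <- 40
  cb <- structure(
    list(centroids = matrix(rnorm(k * 64), k, 64), k = k, d = 64,
         trained_on = k, seed = 0),
    class = "bof_codebook"
  )
  for (i in 1:50) {
    desc <- matrix(rnorm(sample(5:60, 1) * 64), ncol = 64)
    v <- encode_bof(make_kpset(desc), cb)
    # brute-force reassignment, descriptor by descriptor
    counts <- numeric(k)
    for (j in seq_len(nrow(desc))) {
      d2 <- colSums((t(cb$centroids) - desc[j, ])^2)
      counts[which.min(d2)] <- counts[which.min(d2)] + 1
    }
    expect_equal(v$freqs, counts / sum(counts), tolerance = 1e-12)
    expect_equal(sum(v$freqs), 1, tolerance = 1e-9)
    expect_false(v$degenerate)
  }
})

test_that("single-word and zero-keypoint encodings follow the declared contracts", {
  cb <- structure(
    list(centroids = rbind(rep(10, 64), rep(0, 64), rep(-10, 64), rep(20, 64)),
         k = 4, d = 64, trained_on = 4, seed = 0),
    class = "bof_codebook"
  )
  desc <- matrix(rnorm(10 * 64, sd = 0.1), 10, 64) # all nearest word 2
  v <- encode_bof(make_kpset(desc), cb)
  expect_equal(v$freqs, c(0, 1, 0, 0))
  v0 <- encode_bof(make_kpset(matrix(0, 0, 64)), cb)
  expect_equal(v0$freqs, rep(0.25, 4))
  expect_true(v0$degenerate)
})

test_that("tie-breaking picks the lowest centroid index", {
  cb <- structure(
    list(centroids = rbind(c(1, rep(0, 63)), c(1, rep(0, 63)), c(5, rep(0, 63))),
         k = 3, d = 64, trained_on = 3, seed = 0),
    class = "bof_codebook"
  )
  v <- encode_bof(make_kpset(rbind(c(1, rep(0, 63)))), cb)
  expect_equal(v$freqs, c(1, 0, 0))
})

test_that("permuting codebook words permutes histogram entries identically", {
  set.seed(12)
  cb <- structure(
    list(centroids = matrix(rnorm(6 * 64), 6, 64), k = 6, d = 64,
         trained_on = 6, seed = 0),
    class = "bof_codebook"
  )
  kp <- make_kpset(matrix(rnorm(30 * 64), 30, 64))
  v <- encode_bof(kp, cb)
  perm <- c(3, 1, 6, 2, 5, 4)
  cbp <- cb
  cbp$centroids <- cb$centroids[perm, ]
  vp <- encode_bof(kp, cbp)
  expect_equal(vp$freqs, v$freqs[perm])
})

test_that("the codebook refuses descriptors from test-tagged images", {
  desc <- matrix(rnorm(30 * 64), 30, 64)
  expect_error(
    build_codebook(list(make_kpset(desc), make_kpset(desc, split = "test")),
                   k = 2),
    "leakage"
  )
})

test_that("dimension mismatches between detector and codebook are refused", {
  cb <- structure(
    list(centroids = matrix(0, 4, 32), k = 4, d = 32, trained_on = 4, seed = 0),
    class = "bof_codebook"
  )
  expect_error(encode_bof(make_kpset(matrix(rnorm(64), 1, 64)), cb),
               "dimension")
})

test_that("class-average histograms separate apnea from normal on the simulator", {
  feats <- small_features()
  ha <- colMeans(feats$X[feats$label == "A", , drop = FALSE])
  hn <- colMeans(feats$X[feats$label == "N", , drop = FALSE])
  inter <- sum(abs(ha - hn))
  intra <- mean(c(
    rowSums(abs(sweep(feats$X[feats$label == "A", , drop = FALSE], 2, ha))),
    rowSums(abs(sweep(feats$X[feats$label == "N", , drop = FALSE], 2, hn)))
  ))
  expect_gt(inter, intra)
})

test_that("codebooks round-trip through the binary container", {
  set.seed(13)
  desc <- matrix(rnorm(80 * 64), 80, 64)
  cb <- build_codebook(list(make_kpset(desc)), k = 5, seed = 6)
  path <- file.path(withr::local_tempdir(), "cb.bin")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_identical(back$centroids, cb$centroids)
  expect_identical(back$k, cb$k)
  expect_identical(back$seed, cb$seed)
})
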