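# Radiomics: quantization, first-order and gradient statistics, and the
# three texture-matrix families against brute-force oracles.

test_that("quantization is equal-width, monotone and affine-invariant", {
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  q <- quantizeImage(img, roi, Ng = 4)
  expect_equal(sort(as.vector(grayLevels(q))), 1:4)

  expect_warning(qc <- quantizeImage(matrix(5, 3, 3), matrix(TRUE, 3, 3), 4),
                 "constant")
  expect_true(all(grayLevels(qc) == 1L))

  set.seed(7)
  x <- matrix(rnorm(64), 8, 8)
  roi <- matrix(runif(64) < 0.8, 8, 8); roi[1, 1] <- TRUE
  q1 <- quantizeImage(x, roi, 8)
  q2 <- quantizeImage(2 * x + 5, roi, 8)
  expect_identical(grayLevels(q1), grayLevels(q2))
  # monotone in the original intensities
  v <- x[roi]; l <- grayLevels(q1)[roi]
  expect_true(all(diff(l[order(v)]) >= 0))
  # outside ROI is 0, inside is 1..Ng
  expect_true(all(grayLevels(q1)[!roi] == 0))
  expect_true(all(grayLevels(q1)[roi] %in% 1:8))
})

test_that("skewness and kurtosis follow the adjusted Fisher-Pearson forms", {
  fo <- firstOrderFeatures(c(0, 0, 1, 1), nbins = 2)
  v <- featureValues(fo)
  expect_equal(unname(v["skewness"]), 0)
  expect_equal(unname(v["kurtosis"]), -6)
  # uniform histogram over Ng bins has entropy log2(Ng)
  Ng <- 8
  vals <- rep(seq(0, 1, length.out = Ng), each = 5)
  fo2 <- firstOrderFeatures(vals, nbins = Ng)
  expect_equal(unname(featureValues(fo2)["entropy"]), log2(Ng))
  expect_equal(unname(featureValues(fo2)["energy"]), sum(rep(1 / Ng, Ng)^2))
  # constant input: flagged, imputed 0
  foc <- firstOrderFeatures(rep(2, 10))
  expect_setequal(flaggedFeatures(foc), c("skewness", "kurtosis"))
  expect_equal(unname(featureValues(foc)[c("skewness", "kurtosis")]), c(0, 0))
  # against closed-form on random data
  set.seed(1)
  x <- rnorm(50)
  n <- length(x); z <- (x - mean(x)) / sd(x)
  expect_equal(unname(featureValues(firstOrderFeatures(x))["skewness"]),
               n / ((n - 1) * (n - 2)) * sum(z^3))
})

test_that("gradient features are zero on constants, unit on ramps", {
  g <- gradientFeatures(matrix(3, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(unname(featureValues(g)), rep(0, 4))
  expect_setequal(flaggedFeatures(g), c("grad_skewness", "grad_kurtosis"))

  ramp <- matrix(0:4, 1, 5)
  gr <- gradientFeatures(ramp, matrix(TRUE, 1, 5))
  expect_equal(unname(featureValues(gr)["grad_mean"]), 1)
  expect_equal(unname(featureValues(gr)["grad_variance"]), 0)

  # checkerboard has larger mean gradient than its median-smoothed version
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  sm <- medianFilterImage(cb, filterConfig("median", 3))
  roi <- matrix(TRUE, 8, 8)
  expect_gt(featureValues(gradientFeatures(cb, roi))["grad_mean"],
            featureValues(gradientFeatures(sm, roi))["grad_mean"])
})

test_that("GLCM matches hand enumeration and the brute-force oracle", {
  q <- quantizeImage(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE),
                     matrix(TRUE, 2, 2), 2)
  m <- glcm(q, d = 1, offset = c(0L, 1L), symmetric = TRUE, normalize = FALSE)
  expect_equal(counts(m), matrix(c(2, 1, 1, 0), 2, 2))
  mn <- glcm(q, d = 1, offset = c(0L, 1L))
  expect_equal(sum(counts(mn)), 1)
  expect_equal(counts(mn), t(counts(mn)))

  set.seed(42)
  for (i in 1:12) {
    q <- randomQuantized(8, 8, 4, roi_frac = 0.85)
    for (off in textureOffsets(2, 1)) {
      got <- counts(glcm(q, offset = off, normalize = FALSE))
      want <- oracleGLCM(grayLevels(q), roiMask(q), off, 4)
      expect_equal(got, want, ignore_attr = FALSE, tolerance = 0)
    }
  }
})

test_that("GLCM features have the stated degenerate and uniform limits", {
  qc <- suppressWarnings(quantizeImage(matrix(1, 4, 4), matrix(TRUE, 4, 4), 4))
  f <- glcmFeatures(glcm(qc))
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)

  # checkerboard of two levels: every horizontal pair differs by exactly 1
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  qcb <- quantizeImage(cb, matrix(TRUE, 6, 6), 2)
  f2 <- glcmFeatures(glcm(qcb, offset = c(0L, 1L)))
  expect_equal(unname(f2["glcm_contrast"]), 1)

  # uniform p over Ng^2 cells
  u <- new("TextureMatrix", kind = "GLCM",
           counts = matrix(1 / 16, 4, 4), distance = 1L,
           offset = c(0L, 1L), normalized = TRUE)
  expect_equal(unname(glcmFeatures(u)["glcm_entropy"]), 2 * log2(4))
})

test_that("GLRLM matches run enumeration, conserves voxels, oracle agrees", {
  row <- matrix(c(1, 1, 2, 2, 2), 1, 5)
  q <- quantizeImage(row, matrix(TRUE, 1, 5), 2)
  m <- counts(glrlm(q, offset = c(0L, 1L)))
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 3], 1)
  expect_equal(sum(m), 2)

  set.seed(11)
  for (i in 1:12) {
    q <- randomQuantized(8, 8, 4, roi_frac = 0.8)
    for (off in textureOffsets(2, 1)) {
      got <- counts(glrlm(q, off))
      want <- oracleGLRLM(grayLevels(q), roiMask(q), off, 4)
      # pad to common width for comparison
      w <- max(ncol(got), ncol(want))
      pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
      expect_equal(pad(got), pad(want))
      # conservation: sum L * counts = ROI voxels
      expect_equal(sum(sweep(got, 2, seq_len(ncol(got)), "*")),
                   sum(roiMask(q)))
    }
  }
})

test_that("GLRLM features: SRE/LRE bounds and degenerate cases", {
  # all runs length 1 (checkerboard along scan direction)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  q <- quantizeImage(cb, matrix(TRUE, 6, 6), 2)
  f <- glrlmFeatures(glrlm(q, c(0L, 1L)))
  expect_equal(unname(f["glrlm_sre"]), 1)
  expect_equal(unname(f["glrlm_run_fraction"]), 1)

  # one run covering a whole row of length L
  rowq <- suppressWarnings(quantizeImage(matrix(1, 1, 7), matrix(TRUE, 1, 7), 2))
  f2 <- glrlmFeatures(glrlm(rowq, c(0L, 1L)))
  expect_equal(unname(f2["glrlm_lre"]), 49)

  set.seed(5)
  for (i in 1:25) {
    q <- randomQuantized(8, 8, 4)
    f <- glrlmFeatures(glrlm(q, c(0L, 1L)))
    expect_lte(f["glrlm_sre"], 1)
    expect_gte(f["glrlm_lre"], 1)
  }
})

test_that("GLSZM matches connected-component enumeration with 8-connectivity", {
  img <- matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)
  q <- quantizeImage(img, matrix(TRUE, 2, 2), 2)
  m <- counts(glszm(q))
  expect_equal(m[1, 3], 1)   # the three 1-voxels form one zone
  expect_equal(m[2, 1], 1)

  # a diagonal of equal levels is one zone under the infinity norm
  dg <- diag(5); dg[dg == 0] <- 2
  qd <- quantizeImage(dg, matrix(TRUE, 5, 5), 2)
  md <- counts(glszm(qd))
  expect_equal(md[1, 5], 1)

  set.seed(23)
  for (i in 1:12) {
    q <- randomQuantized(8, 8, 4, roi_frac = 0.8)
    got <- counts(glszm(q))
    want <- oracleGLSZM(grayLevels(q), roiMask(q), 4)
    w <- max(ncol(got), ncol(want))
    pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
    expect_equal(pad(got), pad(want))
    expect_equal(sum(sweep(got, 2, seq_len(ncol(got)), "*")), sum(roiMask(q)))
  }
})

test_that("GLSZM features: zone percentage and large-zone emphasis limits", {
  # all zones size 1: a strictly increasing surface quantized to one level
  # per voxel (a two-level checkerboard would still connect diagonally)
  surf <- matrix(seq_len(16), 4, 4)
  qs <- quantizeImage(surf, matrix(TRUE, 4, 4), 16)
  fs <- glszmFeatures(glszm(qs))
  expect_equal(unname(fs["glszm_zone_percentage"]), 1)

  # single whole-ROI zone of size S
  qw <- suppressWarnings(quantizeImage(matrix(2, 3, 3), matrix(TRUE, 3, 3), 4))
  fw <- glszmFeatures(glszm(qw))
  expect_equal(unname(fw["glszm_lze"]), 81)
  expect_equal(unname(fw["glszm_zone_percentage"]), 1 / 9)
})

test_that("full extraction is deterministic, fixed-length, translation-invariant", {
  ph <- smallPhantoms(2, seed = 3)
  v1 <- extractRadiomics(ph[[1]], radiomicsConfig(ng = 8))
  v2 <- extractRadiomics(ph[[1]], radiomicsConfig(ng = 8))
  expect_identical(featureValues(v1), featureValues(v2))
  expect_length(featureValues(v1), 29)   # 11 + 4 + 4 + 5 + 5 per channel

  # translation of the whole ROI+image leaves features unchanged
  img <- sampleImage(ph[[1]]); mask <- sampleMask(ph[[1]])
  d <- dim(img)
  sh <- array(0, d); shm <- array(FALSE, d[-1])
  sh[, 3:d[2], 3:d[3]] <- img[, 1:(d[2] - 2), 1:(d[3] - 2)]
  shm[3:d[2], 3:d[3]] <- mask[1:(d[2] - 2), 1:(d[3] - 2)]
  s2 <- new("VolumeSample", image = sh, mask = shm,
            foreground = sh[1, , ] != 0, label = 1L)
  v3 <- extractRadiomics(s2, radiomicsConfig(ng = 8))
  expect_equal(featureValues(v3), featureValues(v1), tolerance = 1e-12)

  # 90-degree rotation leaves direction-averaged features unchanged
  rot <- function(m) t(m[nrow(m):1, ])
  s3 <- new("VolumeSample",
            image = array(rot(img[1, , ]), c(1, d[3], d[2])),
            mask = rot(mask), foreground = rot(sampleForeground(ph[[1]])),
            label = 1L)
  v4 <- extractRadiomics(s3, radiomicsConfig(ng = 8))
  expect_equal(featureValues(v4), featureValues(v1), tolerance = 1e-10)

  # classes with different correlation lengths separate on GLCM contrast
  ph2 <- smallPhantoms(60, sep = 1, seed = 9)
  tab <- radiomicsTable(ph2, radiomicsConfig(ng = 8))
  p <- wilcox.test(ch1_glcm_contrast ~ label, data = tab)$p.value
  expect_lt(p, 0.01)
})
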