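# Augmentation: involution and congruence of flips, frequency calibration,
# range clipping, zoom shape preservation, biased-crop containment.

make2d <- function(seed = 1) smallPhantoms(1, seed = seed)[[1]]

test_that("flips are involutive, congruent and calibrated to p = 0.5", {
  s <- make2d()
  spec1 <- augmentationSpec(p_flip_per_axis = 1)
  set.seed(1); f1 <- randomFlip(s, spec1)
  set.seed(1); f2 <- randomFlip(f1, spec1)
  expect_identical(sampleImage(f2), sampleImage(s))
  expect_identical(sampleMask(f2), sampleMask(s))

  # flipping permutes voxels: multiset unchanged; mask moves with image
  expect_equal(sort(as.vector(sampleImage(f1))), sort(as.vector(sampleImage(s))))
  expect_equal(sum(sampleMask(f1)), sum(sampleMask(s)))
  expect_equal(sampleImage(f1)[1, , ][sampleMask(f1)][order(sampleImage(f1)[1, , ][sampleMask(f1)])],
               sampleImage(s)[1, , ][sampleMask(s)][order(sampleImage(s)[1, , ][sampleMask(s)])])

  # per-axis frequency over many draws within the binomial 99% CI; encode
  # row and column indices so each axis flip is separately detectable from
  # the corner voxel
  set.seed(33)
  enc <- outer(1:2, 1:4, function(i, j) i + 10 * j)
  tiny <- new("VolumeSample", image = array(enc, c(1, 2, 4)),
              mask = array(FALSE, c(2, 4)), foreground = array(TRUE, c(2, 4)),
              label = 0L)
  spec <- augmentationSpec()
  draws <- replicate(1000, {
    corner <- sampleImage(randomFlip(tiny, spec))[1, 1, 1]
    c(row = corner %% 10 == 2, col = corner >= 40)
  })
  for (ax in 1:2) {
    expect_gte(mean(draws[ax, ]), 0.46)
    expect_lte(mean(draws[ax, ]), 0.54)
  }
})

test_that("blur never increases variance and fires at p = 0.15", {
  s <- make2d(2)
  spec <- augmentationSpec(p_blur = 1)
  set.seed(2)
  b <- randomGaussianBlur(s, spec)
  expect_lte(var(as.vector(sampleImage(b))), var(as.vector(sampleImage(s))))
  # constant image unchanged
  cst <- new("VolumeSample", image = array(3, c(1, 8, 8)),
             mask = array(FALSE, c(8, 8)), foreground = array(TRUE, c(8, 8)),
             label = 0L)
  set.seed(3)
  expect_equal(sampleImage(randomGaussianBlur(cst, spec)),
               sampleImage(cst), tolerance = 1e-12)

  # application frequency on a non-constant image, binomial 99% CI at n=2000
  set.seed(44)
  n_applied <- sum(replicate(2000, {
    out <- randomGaussianBlur(s, augmentationSpec())
    !identical(sampleImage(out), sampleImage(s))
  }))
  expect_gte(n_applied / 2000, 0.13)
  expect_lte(n_applied / 2000, 0.17)
})

test_that("brightness, contrast and noise respect their contracts", {
  s <- make2d(3)
  # brightness factor multiplies; identity at factor 1 is a no-op draw
  spec <- augmentationSpec(p_brightness = 1, brightness_range = c(1, 1))
  set.seed(1)
  expect_equal(sampleImage(randomBrightness(s, spec)), sampleImage(s))

  # contrast never exceeds the original range
  specc <- augmentationSpec(p_contrast = 1, contrast_range = c(1.5, 1.5))
  set.seed(2)
  ct <- randomContrast(s, specc)
  expect_gte(min(sampleImage(ct)), min(sampleImage(s)))
  expect_lte(max(sampleImage(ct)), max(sampleImage(s)))

  # noise applies to foreground only: the zero background stays zero
  specn <- augmentationSpec(p_noise = 1)
  set.seed(3)
  nz <- randomNoise(s, specn)
  fg <- sampleForeground(s)
  expect_true(all(sampleImage(nz)[1, , ][!fg] == 0))
  expect_false(identical(sampleImage(nz)[1, , ][fg], sampleImage(s)[1, , ][fg]))
})

test_that("zoom preserves shape and is identity at factor 1", {
  s <- make2d(4)
  spec1 <- augmentationSpec(p_zoom = 1, zoom_range = c(1, 1))
  set.seed(1)
  expect_identical(sampleImage(randomZoom(s, spec1)), sampleImage(s))
  specz <- augmentationSpec(p_zoom = 1, zoom_range = c(1.3, 1.4))
  set.seed(2)
  z <- randomZoom(s, specz)
  expect_identical(dim(sampleImage(z)), dim(sampleImage(s)))
  expect_identical(dim(sampleMask(z)), dim(sampleMask(s)))
  # mask stays logical under nearest-neighbor interpolation
  expect_type(sampleMask(z), "logical")
})

test_that("biased crop has fixed output shape and honors the mask branch", {
  ph <- generatePhantoms(phantomSpec(2, c(40, 40), n_channels = 2, seed = 6))
  s <- ph[[1]]
  spec <- augmentationSpec(crop_shape = c(2L, 16L, 16L),
                           p_biased_crop_foreground = 1)
  set.seed(5)
  cr <- biasedCrop(s, spec)
  expect_identical(dim(sampleImage(cr)), c(2L, 16L, 16L))

  # single-voxel mask: every biased crop contains that voxel
  m1 <- array(FALSE, c(40, 40)); m1[13, 29] <- TRUE
  s1 <- new("VolumeSample", image = sampleImage(s), mask = m1,
            foreground = sampleForeground(s), label = 1L)
  set.seed(6)
  hits <- replicate(200, sum(sampleMask(biasedCrop(s1, spec))))
  expect_true(all(hits == 1))

  # mask covering everything: every crop contains mask voxels
  mall <- array(TRUE, c(40, 40))
  sall <- new("VolumeSample", image = sampleImage(s), mask = mall,
              foreground = sampleForeground(s), label = 1L)
  set.seed(7)
  expect_true(all(replicate(20, sum(sampleMask(biasedCrop(sall, spec)))) > 0))

  # empty mask falls back to uniform with a warning
  s0 <- new("VolumeSample", image = sampleImage(s),
            mask = array(FALSE, c(40, 40)),
            foreground = sampleForeground(s), label = 0L)
  set.seed(8)
  expect_warning(biasedCrop(s0, spec), "empty")

  # smaller-than-patch input is zero-padded
  tinyph <- smallPhantoms(1, seed = 7, shape = c(12, 12))[[1]]
  set.seed(9)
  crp <- biasedCrop(tinyph, augmentationSpec(crop_shape = c(1L, 16L, 16L),
                                             p_biased_crop_foreground = 0))
  expect_identical(dim(sampleImage(crp)), c(1L, 16L, 16L))
})

test_that("the augmentation stream is seed-deterministic and label-preserving", {
  s <- make2d(8)
  spec <- augmentationSpec(crop_shape = c(1L, 24L, 24L))
  set.seed(123); a <- augmentSample(s, spec)
  set.seed(123); b <- augmentSample(s, spec)
  expect_identical(sampleImage(a), sampleImage(b))
  expect_identical(sampleMask(a), sampleMask(b))
  expect_identical(sampleLabel(a), sampleLabel(s))
})
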