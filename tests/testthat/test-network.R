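# Network: Seq-ResNet block contracts, up/down scale-change modules, model
# assembly, initialization statistics, gradient flow and a tiny training
# smoke.  Heavier training checks live in the acceptance suite.

tinyConfig <- function(in_channels = 2L, fc_dim = 16L) {
  fusionNetConfig(
    in_channels = in_channels,
    stage_plan = data.frame(blocks = c(1L, 1L), channels = c(8L, 12L),
                            change = c("down", "none")),
    fc_dim = fc_dim)
}

test_that("Seq-ResNet block preserves shape and has the declared structure", {
  set.seed(1)
  for (C in c(8L, 16L, 33L)) {
    blk <- fusionrad:::nnSeqRes(C)
    flat <- fusionrad:::.flattenParams(blk)
    for (nm in names(flat))
      if (grepl("\\.w$", nm)) flat[[nm]][] <- rnorm(length(flat[[nm]]), 0, 0.1)
    blk <- fusionrad:::.assignParams(blk, flat)
    x <- array(rnorm(12 * 10 * C * 2), c(12, 10, C, 2))
    y <- fusionrad:::nnForward(blk, x, training = TRUE)$y
    expect_identical(dim(y), dim(x))
  }
  # 15 reduced channels in 5 subspaces of 3
  blk <- fusionrad:::nnSeqRes(8L)
  expect_equal(dim(blk$sub$reduce$sub$s01$params$w), c(1, 1, 8, 15))
  expect_length(grep("^b", names(blk$sub)), 5)
  # the first subspace is processed-free
  expect_length(blk$sub$b0$sub, 0)
  # hierarchically increasing stage counts for the others
  expect_length(blk$sub$b1$sub, 1)
  expect_length(blk$sub$b2$sub, 2)
  expect_length(blk$sub$b3$sub, 3)
  expect_length(blk$sub$b4$sub, 4)
})

test_that("zero-weight Seq-ResNet block reduces to the identity shortcut", {
  blk <- fusionrad:::nnSeqRes(6L)   # fresh block: all weights still zero
  x <- array(rnorm(8 * 8 * 6 * 3), c(8, 8, 6, 3))
  y <- fusionrad:::nnForward(blk, x, training = TRUE)$y
  expect_equal(y, x, tolerance = 0)
})

test_that("up/down modules double and halve spatial dims, channels preserved", {
  set.seed(2)
  up <- fusionrad:::nnUpDown(16L, "up")
  dn <- fusionrad:::nnUpDown(16L, "down")
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  yu <- fusionrad:::nnForward(up, x, training = TRUE)$y
  expect_identical(dim(yu), c(16L, 16L, 16L, 2L))
  yd <- fusionrad:::nnForward(dn, yu, training = TRUE)$y
  expect_identical(dim(yd), dim(x))

  # zero input stays zero: no bias leak anywhere in the module
  z <- array(0, c(8, 8, 16, 2))
  expect_true(all(fusionrad:::nnForward(up, z, training = TRUE)$y == 0))
  expect_true(all(fusionrad:::nnForward(dn, z, training = TRUE)$y == 0))

  # odd spatial dims are rejected for downsampling
  xo <- array(rnorm(7 * 8 * 16 * 1), c(7, 8, 16, 1))
  expect_error(fusionrad:::nnForward(dn, xo, training = TRUE), "even")

  # constant input gives a spatially constant downsampled output
  set.seed(3)
  dn2 <- fusionrad:::nnUpDown(4L, "down")
  flat <- fusionrad:::.flattenParams(dn2)
  for (nm in names(flat))
    if (grepl("\\.w$", nm)) flat[[nm]][] <- rnorm(length(flat[[nm]]), 0, 0.1)
  dn2 <- fusionrad:::.assignParams(dn2, flat)
  cst <- array(rep(c(1, 2, 3, 4), each = 16 * 16), c(16, 16, 4, 1))
  yc <- fusionrad:::nnForward(dn2, cst, training = TRUE)$y
  # interior pixels (away from padding effects) are constant per channel
  inner <- yc[3:6, 3:6, , 1, drop = FALSE]
  for (ch in 1:4) expect_lt(diff(range(inner[, , ch, 1])), 1e-10)
})

test_that("the default model has 37 blocks; depth_scale shrinks it", {
  net <- buildFusionNet(fusionNetConfig())
  expect_equal(nSeqResBlocks(net), 37L)
  small <- buildFusionNet(fusionNetConfig(depth_scale = 0.25))
  expect_equal(nSeqResBlocks(small), 10L)   # round(c(6,8,12,8,3)/4), min 1
  expect_lt(nParameters(small), nParameters(net))
  expect_error(fusionNetConfig(stage_plan = data.frame(blocks = 1)), "stage_plan")
})

test_that("forward pass honors the shape contract across random tiny configs", {
  set.seed(4)
  for (i in 1:3) {
    C <- sample(1:3, 1)
    fc <- sample(c(8L, 16L), 1)
    net <- buildFusionNet(tinyConfig(C, fc))
    x <- array(rnorm(16 * 16 * C * 3), c(16, 16, C, 3))
    fw <- fusionrad:::.netForward(net, x, training = FALSE)
    expect_identical(dim(fw$logits), c(3L, 2L))
    expect_identical(dim(fw$features), c(3L, fc))
  }
})

test_that("a Seq-ResNet block is leaner than a plain residual block", {
  for (C in c(32L, 64L)) {
    blk <- fusionrad:::nnSeqRes(C)
    nblk <- sum(vapply(fusionrad:::.flattenParams(blk), length, integer(1)))
    plain <- 2L * C * C * 9L   # two full 3x3 convolutions at equal width
    expect_lt(nblk, plain)
  }
})

test_that("every parameter tensor receives gradient (no dead branch)", {
  set.seed(5)
  net <- buildFusionNet(tinyConfig())
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  g <- networkGradients(net, x, c(0L, 1L, 0L, 1L))
  expect_true(is.finite(g$loss))
  flows <- vapply(g$grads, function(z) any(z != 0), logical(1))
  expect_true(all(flows))
  # gradient names align one-to-one with parameter names
  expect_identical(names(g$grads),
                   names(fusionrad:::.modelParams(net@layers)))
})

test_that("weight initialization draws from N(0, 0.01) with zero biases", {
  set.seed(6)
  net <- buildFusionNet(tinyConfig(2L, 64L))
  flat <- fusionrad:::.modelParams(net@layers)
  w <- unlist(flat[grep("\\.w$", names(flat))])
  expect_gt(length(w), 2000)
  expect_lt(abs(sd(w) - 0.1), 0.005)
  expect_lt(abs(mean(w)), 0.005)
  expect_gt(shapiro.test(sample(w, 500))$p.value, 0.01)
  b <- unlist(flat[grep("\\.b$", names(flat))])
  expect_true(all(b == 0))
})

test_that("training declines in loss, is seed-stable, and rejects one class", {
  ph <- smallPhantoms(16, sep = 1, seed = 41, shape = c(16, 16))
  pre <- lapply(ph, function(p)
    preprocessVolume(sampleImage(p), sampleMask(p), sampleLabel(p),
                     resize = c(16, 16))$sample)
  net <- buildFusionNet(tinyConfig())
  cfg <- trainConfig(max_epochs = 2L, batch_size = 8L, seed = 9L)
  tr1 <- trainFusionNet(net, pre, config = cfg)
  tr2 <- trainFusionNet(net, pre, config = cfg)
  expect_identical(tr1@history$loss, tr2@history$loss)
  expect_length(tr1@history$loss, 2L)
  expect_true(all(is.finite(tr1@history$loss)))
  expect_error(trainFusionNet(net, pre[c(1, 3, 5)],
                              config = cfg), "both classes")

  # deep features: eval-mode determinism and fixed dimension
  f1 <- extractDeepFeatures(tr1, pre)
  f2 <- extractDeepFeatures(tr1, pre)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(16L, 16L))
  expect_warning(extractDeepFeatures(net, pre[1:2]), "untrained")
})
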