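# Fusion and multi-kernel SVM: table joins, kernel functions, selection by
# inner CV, stratification, leakage control.

fakeTables <- function(n = 40, d1 = 6, d2 = 4, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), n / 2)
  ids <- sprintf("S%03d", seq_len(n))
  deep <- data.frame(sample_id = ids,
                     matrix(rnorm(n * d1) + labels, n, d1,
                            dimnames = list(NULL, sprintf("deep_%d", 1:d1))),
                     label = labels, check.names = FALSE)
  rad <- data.frame(sample_id = ids,
                    matrix(rnorm(n * d2) - labels, n, d2,
                           dimnames = list(NULL, sprintf("rad_%d", 1:d2))),
                    label = labels, check.names = FALSE)
  list(deep = deep, rad = rad, labels = labels)
}

test_that("fusion joins on sample_id and is order-independent", {
  tb <- fakeTables()
  fused <- fuseFeatures(tb$deep, tb$rad)
  expect_equal(ncol(fused), 2 + 6 + 4)
  # permuting one table's rows changes nothing after the keyed join
  perm <- tb$rad[sample(nrow(tb$rad)), ]
  fused2 <- fuseFeatures(tb$deep, perm)
  expect_equal(fused2, fused)
  # mismatched ids are reported
  bad <- tb$rad; bad$sample_id[3] <- "NOPE"
  expect_error(fuseFeatures(tb$deep, bad), "NOPE")
})

test_that("train-split standardization has zero mean and unit scale", {
  set.seed(2)
  train <- matrix(rnorm(200, 5, 3), 50, 4)
  test <- matrix(rnorm(40, 5, 3), 10, 4)
  st <- standardizeFeatures(train, test)
  expect_lt(max(abs(colMeans(st$train))), 1e-9)
  expect_equal(unname(apply(st$train, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # test uses train parameters, not its own
  expect_false(all(abs(colMeans(st$test)) < 1e-9))
})

test_that("kernel functions match their closed forms", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(kernelEval("rbf", x, x, gamma = 0.7), 1)
  expect_equal(kernelEval("linear", x, y), sum(x * y))
  expect_equal(kernelEval("polynomial", x, y, gamma = 1, degree = 1, coef0 = 0),
               kernelEval("linear", x, y))
  expect_error(kernelEval("sigmoid", x, y), "unknown")
  # linear Gram matrix equals X X^T
  X <- matrix(rnorm(30), 6, 5)
  G <- outer(seq_len(6), seq_len(6),
             Vectorize(function(i, j) kernelEval("linear", X[i, ], X[j, ])))
  expect_equal(G, X %*% t(X), tolerance = 1e-10)
})

test_that("kernel selection finds separable and XOR structure", {
  # linearly separable blobs: selected model fits training data perfectly
  set.seed(4)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  x <- matrix(rnorm(n * 2, sd = 0.3), n, 2) + 3 * cbind(y, y)
  m <- fitMultikernelSVM(x, y, seed = 1)
  pred <- as.integer(predict(m@fit, x) == "malignant")
  expect_equal(pred, y)

  # balanced XOR pattern: a biased linear separator tops out near 0.75 (it
  # can isolate at most one of the four clusters), while rbf/polynomial
  # resolve it fully, so a nonlinear kernel must be selected
  set.seed(5)
  n <- 200
  q <- rep(1:4, each = n / 4)
  sg <- cbind(c(-1, -1, 1, 1)[q], c(-1, 1, -1, 1)[q])
  cx <- matrix(rnorm(n * 2, sd = 0.25), n, 2) + 2 * sg
  yx <- as.integer(cx[, 1] * cx[, 2] > 0)
  mx <- fitMultikernelSVM(cx, yx, seed = 2)
  expect_true(mx@kernel %in% c("rbf", "polynomial"))
  rep_lin <- mx@report[mx@report$kernel == "linear", ]
  best_nonlin <- max(mx@report$inner_cv_accuracy[mx@report$kernel != "linear"])
  expect_lte(max(rep_lin$inner_cv_accuracy), 0.85)
  expect_gt(best_nonlin, 0.95)

  expect_error(fitMultikernelSVM(x[y == 1, ], y[y == 1]), "class")
})

test_that("explicit kernel decision function reproduces the solver", {
  set.seed(6)
  n <- 50
  y <- rep(c(0L, 1L), n / 2)
  x <- matrix(rnorm(n * 3), n, 3) + cbind(y, 0, -y)
  for (k in c("linear", "polynomial", "rbf")) {
    m <- fitMultikernelSVM(x, y, kernels = k, seed = 3)
    f_mine <- svmDecisionFunction(m, x)
    f_solver <- fusionrad:::.svmScores(m@fit, x)
    expect_equal(f_mine, f_solver, tolerance = 1e-8)
    expect_equal(as.integer(f_mine > 0),
                 as.integer(predict(m@fit, x) == "malignant"))
  }
})

test_that("stratified folds partition samples and balance classes", {
  labels <- c(rep(0L, 23), rep(1L, 17))
  plan <- cvPlan(labels, 5, seed = 9)
  expect_equal(sort(unique(plan$folds)), 1:5)
  expect_equal(length(plan$folds), 40)
  # every sample in exactly one fold; class counts within 1 of proportional
  for (f in 1:5) {
    expect_gte(sum(plan$folds == f & labels == 1), 3)
    expect_lte(sum(plan$folds == f & labels == 1), 4)
  }
})

test_that("cross-validation aggregates per-fold metrics exactly", {
  tb <- fakeTables(n = 60, seed = 7)
  fused <- fuseFeatures(tb$deep, tb$rad)
  cv <- crossValidate(fused, n_folds = 5, seed = 11, kernels = "linear")
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(unname(cv$aggregate$mean["accuracy"]),
               mean(cv$per_fold$accuracy), tolerance = 1e-12)
  expect_equal(unname(cv$aggregate$sd["f1"]), sd(cv$per_fold$f1),
               tolerance = 1e-12)
  # deterministic given the seed
  cv2 <- crossValidate(fused, n_folds = 5, seed = 11, kernels = "linear")
  expect_identical(cv$per_fold, cv2$per_fold)
  # informative features classify well
  expect_gt(cv$aggregate$mean["accuracy"], 0.9)
})

test_that("a test-fold-only informative feature cannot leak into selection", {
  set.seed(8)
  n <- 60
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  plan <- cvPlan(labels, 5, seed = 13)
  test_rows <- plan$folds == 1
  x2 <- x
  # make the last feature perfectly informative, but only on fold 1's rows
  x2[test_rows, 5] <- labels[test_rows] * 10
  st1 <- standardizeFeatures(x[!test_rows, ], x[test_rows, ])
  st2 <- standardizeFeatures(x2[!test_rows, ], x2[test_rows, ])
  m1 <- fitMultikernelSVM(st1$train, labels[!test_rows], seed = 21)
  m2 <- fitMultikernelSVM(st2$train, labels[!test_rows], seed = 21)
  expect_identical(m1@report, m2@report)
  expect_identical(m1@kernel, m2@kernel)
})
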