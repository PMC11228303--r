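# Feature fusion and multi-kernel SVM classification.  Deep and radiomics
# feature tables are joined on sample_id and concatenated; a kernel (linear,
# polynomial, RBF) and its hyperparameters are selected by inner stratified
# cross-validation on training data only, and the outer stratified k-fold
# protocol reports per-fold and aggregate metrics.  The SVM dual problem is
# solved by libsvm (through e1071); kernel evaluation, selection and the CV
# protocol live here.

#' Fuse deep and radiomics feature tables
#'
#' Joins the two tables on `sample_id` (order-independent) and concatenates
#' their feature columns.  No scaling is applied here: per-feature
#' standardization is fitted on training folds inside [crossValidate()].
#'
#' @param deep data.frame with `sample_id`, feature columns and `label`.
#' @param radiomics data.frame with the same structure.
#' @return data.frame `sample_id`, deep features, radiomics features, `label`.
#' @export
fuseFeatures <- function(deep, radiomics) {
  for (tb in list(deep, radiomics))
    if (!all(c("sample_id", "label") %in% names(tb)))
      stop("feature tables need sample_id and label columns")
  miss1 <- setdiff(deep$sample_id, radiomics$sample_id)
  miss2 <- setdiff(radiomics$sample_id, deep$sample_id)
  if (length(miss1) || length(miss2))
    stop("sample_id mismatch between tables: ",
         paste(c(miss1, miss2), collapse = ", "))
  rad <- radiomics[match(deep$sample_id, radiomics$sample_id), ]
  if (any(rad$label != deep$label))
    stop("label mismatch between tables for aligned sample_ids")
  dfeat <- deep[, setdiff(names(deep), c("sample_id", "label")), drop = FALSE]
  rfeat <- rad[, setdiff(names(rad), c("sample_id", "label")), drop = FALSE]
  out <- data.frame(sample_id = deep$sample_id, dfeat, rfeat,
                    label = deep$label, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-feature standardization fitted on a training split
#'
#' @param train,test numeric matrices (columns = features).
#' @return list with standardized `train` and `test` matrices; constant
#'   features get a unit scale.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  std <- function(m) sweep(sweep(m, 2, mu, "-"), 2, sg, "/")
  list(train = std(train), test = if (!is.null(test)) std(test))
}

#' Evaluate an SVM kernel function
#'
#' Linear: `<x, y>`; polynomial: `(gamma <x, y> + coef0)^degree`; RBF:
#' `exp(-gamma ||x - y||^2)`.
#'
#' @param kind `"linear"`, `"polynomial"` or `"rbf"`.
#' @param x,y numeric vectors of equal length.
#' @param gamma,degree,coef0 kernel hyperparameters.
#' @return scalar kernel value.
#' @export
kernelEval <- function(kind, x, y, gamma = 1, degree = 3L, coef0 = 0) {
  switch(kind,
         linear = sum(x * y),
         polynomial = (gamma * sum(x * y) + coef0)^degree,
         rbf = exp(-gamma * sum((x - y)^2)),
         stop("unknown kernel: ", kind))
}

# labels as a factor with fixed level order so the decision-value sign is
# stable: positive decision value = malignant
.svmLabels <- function(labels) factor(labels, levels = c(1, 0),
                                      labels = c("malignant", "benign"))

.fitSvm <- function(x, y, kind, C, gamma, degree, coef0) {
  e1071::svm(x, .svmLabels(y),
             type = "C-classification", scale = FALSE,
             kernel = if (kind == "rbf") "radial" else kind,
             cost = C, gamma = gamma, degree = degree, coef0 = coef0)
}

.svmScores <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  s <- dv[, 1]
  # orient so larger = malignant
  if (!grepl("^malignant", colnames(dv)[1])) s <- -s
  unname(s)
}

#' Stratified cross-validation plan
#'
#' Partitions samples into `n_folds` folds preserving class proportions to
#' within one sample per fold.
#'
#' @param labels integer 0/1 labels.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return list of class `"CVPlan"` with `folds` (integer assignment per
#'   sample), `n_folds` and `seed`.
#' @export
cvPlan <- function(labels, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  if (any(tabulate(folds, n_folds) == 0))
    stop("too few samples for ", n_folds, " folds")
  structure(list(folds = folds, n_folds = n_folds, seed = as.integer(seed)),
            class = "CVPlan")
}

# candidate grid: C x (gamma, degree) per kernel; ties resolved by kernel
# order (linear, polynomial, rbf), then smaller C, gamma, degree
.kernelGrid <- function(kernels, d_features) {
  Cs <- c(0.1, 1, 10)
  gammas <- sort(unique(c(1 / d_features, 0.01, 0.1)))
  grid <- list()
  for (k in kernels) {
    if (k == "linear") {
      for (C in Cs)
        grid <- c(grid, list(list(kind = "linear", C = C, gamma = 1,
                                  degree = 1L, coef0 = 0)))
    } else if (k == "polynomial") {
      for (C in Cs) for (g in gammas) for (dg in c(2L, 3L))
        grid <- c(grid, list(list(kind = "polynomial", C = C, gamma = g,
                                  degree = dg, coef0 = 1)))
    } else if (k == "rbf") {
      for (C in Cs) for (g in gammas)
        grid <- c(grid, list(list(kind = "rbf", C = C, gamma = g,
                                  degree = 1L, coef0 = 0)))
    } else stop("unknown kernel: ", k)
  }
  grid
}

#' Fit an SVM with kernel selection by inner cross-validation
#'
#' Scores every kernel/hyperparameter candidate by stratified inner CV
#' accuracy on the training data only, then refits the best candidate on all
#' of it.  Ties break by kernel order (linear, polynomial, rbf), then the
#' smaller `C`, `gamma` and `degree`.
#'
#' @param x numeric feature matrix (training data, already standardized).
#' @param labels integer 0/1 labels (1 = malignant).
#' @param kernels candidate kernels.
#' @param inner_folds inner stratified folds (default 3).
#' @param seed RNG seed for the inner plan.
#' @return an [SVMModel-class]; `@report` holds per-candidate inner-CV
#'   accuracy.
#' @export
fitMultikernelSVM <- function(x, labels, kernels = c("linear", "polynomial",
                                                     "rbf"),
                              inner_folds = 3L, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need at least 2 samples per class")
  grid <- .kernelGrid(kernels, ncol(x))
  plan <- cvPlan(labels, inner_folds, seed = deriveSeed(seed, "inner-cv"))
  acc <- vapply(grid, function(g) {
    hits <- 0L
    for (f in seq_len(plan$n_folds)) {
      tr <- plan$folds != f
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      fit <- .fitSvm(x[tr, , drop = FALSE], labels[tr], g$kind, g$C, g$gamma,
                     g$degree, g$coef0)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      hits <- hits + sum((pred == "malignant") == (labels[!tr] == 1))
    }
    hits / length(labels)
  }, numeric(1))
  report <- data.frame(kernel = vapply(grid, `[[`, "", "kind"),
                       C = vapply(grid, `[[`, 0, "C"),
                       gamma = vapply(grid, `[[`, 0, "gamma"),
                       degree = vapply(grid, function(g) as.numeric(g$degree), 0),
                       inner_cv_accuracy = acc)
  korder <- match(report$kernel, c("linear", "polynomial", "rbf"))
  best <- order(-acc, korder, report$C, report$gamma, report$degree)[1]
  g <- grid[[best]]
  fit <- .fitSvm(x, labels, g$kind, g$C, g$gamma, g$degree, g$coef0)
  new("SVMModel", fit = fit, kernel = g$kind,
      hyperparams = list(C = g$C, gamma = g$gamma, degree = g$degree,
                         coef0 = g$coef0),
      report = report)
}

#' Decision function of a fitted SVM via explicit kernel evaluation
#'
#' Computes `f(x) = sum_i alpha_i k(m_i, x) + b` from the model's support
#' vectors and dual coefficients using [kernelEval()].  Exists as an
#' independent route to the solver's own `predict`, and as the documented
#' meaning of the fitted model.
#'
#' @param model an [SVMModel-class].
#' @param x matrix of points to evaluate.
#' @return numeric vector of signed decision values (positive = malignant).
#' @export
svmDecisionFunction <- function(model, x) {
  fit <- model@fit
  sv <- fit$SV
  coefs <- fit$coefs[, 1]
  hp <- model@hyperparams
  f <- apply(as.matrix(x), 1, function(p) {
    sum(coefs * apply(sv, 1, function(m)
      kernelEval(model@kernel, m, p, hp$gamma, hp$degree, hp$coef0))) - fit$rho[1]
  })
  # libsvm orients the decision value toward its internally first label
  # (order of first occurrence in the training data); flip when that is not
  # the malignant class
  if (fit$levels[fit$labels[1]] != "malignant") f <- -f
  unname(f)
}

#' Stratified k-fold cross-validation of the fused classifier
#'
#' For each outer fold: standardization is fitted on the training split,
#' kernel and hyperparameters are selected by inner CV on the training split
#' only, the model is refit and evaluated on the held-out fold.  Reports
#' per-fold sensitivity, specificity, precision, accuracy, F1 and AUC, their
#' mean and sd, and the out-of-fold decision scores.
#'
#' @param features numeric matrix or a feature data.frame with `sample_id` /
#'   `label` columns.
#' @param labels integer 0/1 labels (taken from `features` when omitted).
#' @param plan a [cvPlan()]; built from `n_folds`/`seed` when omitted.
#' @param kernels candidate kernels.
#' @param n_folds,seed used when `plan` is missing.
#' @return list with `per_fold` (data.frame), `aggregate` (mean and sd),
#'   `scores` (out-of-fold decision values), `selected` (kernel per fold)
#'   and `reports` (inner-CV selection report per fold).
#' @export
crossValidate <- function(features, labels = NULL, plan = NULL,
                          kernels = c("linear", "polynomial", "rbf"),
                          n_folds = 5L, seed = 1L) {
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$label
    features <- as.matrix(features[, setdiff(names(features),
                                             c("sample_id", "label")),
                                   drop = FALSE])
  }
  labels <- as.integer(labels)
  if (is.null(plan)) plan <- cvPlan(labels, n_folds, seed)
  scores <- numeric(length(labels))
  per <- NULL
  selected <- character(plan$n_folds)
  reports <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$folds != f
    if (length(unique(labels[!tr])) < 2L)
      stop("fold ", f, " does not contain both classes")
    st <- standardizeFeatures(features[tr, , drop = FALSE],
                              features[!tr, , drop = FALSE])
    model <- fitMultikernelSVM(st$train, labels[tr], kernels,
                               seed = deriveSeed(plan$seed, paste0("fold", f)))
    selected[f] <- model@kernel
    reports[[f]] <- model@report
    sc <- .svmScores(model@fit, st$test)
    scores[!tr] <- sc
    pred <- as.integer(sc > 0)
    cm <- confusionCounts(labels[!tr], pred)
    pr <- prf(cm)
    auc <- if (length(unique(labels[!tr])) == 2L)
      rocAuc(sc, labels[!tr])$auc else NA_real_
    per <- rbind(per, data.frame(
      fold = f,
      sensitivity = pr["recall"],
      specificity = if ((cm["TN"] + cm["FP"]) > 0)
        cm["TN"] / (cm["TN"] + cm["FP"]) else 0,
      precision = pr["precision"],
      accuracy = (cm["TP"] + cm["TN"]) / sum(cm),
      f1 = pr["f"],
      auc = auc, row.names = NULL))
  }
  metrics <- setdiff(names(per), "fold")
  list(per_fold = per,
       aggregate = list(mean = colMeans(per[metrics]),
                        sd = apply(per[metrics], 2, sd)),
       scores = scores, selected = selected, reports = reports, plan = plan)
}
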