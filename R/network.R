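# FusionNet: stem convolution, encoder stages of Seq-ResNet blocks separated
# by back-projection downsampling modules, one upsampling stage, global
# average pooling and a fully connected head producing the deep feature
# vector and the class logits.

#' FusionNet configuration
#'
#' The default stage plan distributes 37 Seq-ResNet blocks over five
#' resolution stages — (6, 8, 12, 8, 3) blocks — with back-projection
#' downsampling after each of the first three stages and one upsampling
#' module after the fourth.  `depth_scale < 1` shrinks each stage's block
#' count proportionally (at least one block per stage) for desk-scale models
#' with identical topology.
#'
#' @param in_channels input channels (e.g. modalities + foreground one-hot).
#' @param stage_plan data.frame with columns `blocks`, `channels`, `change`
#'   (`"down"`, `"up"` or `"none"`, applied after the stage).
#' @param fc_dim deep feature dimension (default 256).
#' @param n_classes number of classes (default 2).
#' @param depth_scale block-count multiplier (default 1).
#' @return list of class `"FusionNetConfig"`.
#' @export
fusionNetConfig <- function(in_channels = 5L,
                            stage_plan = data.frame(
                              blocks = c(6L, 8L, 12L, 8L, 3L),
                              channels = c(24L, 32L, 48L, 32L, 24L),
                              change = c("down", "down", "down", "up", "none")),
                            fc_dim = 256L, n_classes = 2L, depth_scale = 1) {
  if (!all(c("blocks", "channels", "change") %in% names(stage_plan)))
    stop("stage_plan needs columns blocks, channels, change")
  if (!all(stage_plan$change %in% c("down", "up", "none")))
    stop("stage_plan change must be down, up or none")
  if (any(stage_plan$blocks < 1)) stop("each stage needs at least one block")
  if (depth_scale <= 0) stop("depth_scale must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 stage_plan = stage_plan, fc_dim = as.integer(fc_dim),
                 n_classes = as.integer(n_classes), depth_scale = depth_scale),
            class = "FusionNetConfig")
}

#' Build a FusionNet model
#'
#' Assembles stem convolution, Seq-ResNet stages with channel transitions and
#' up/down back-projection modules, global average pooling and the fully
#' connected head.  Weights are initialized by [initializeWeights()] using
#' the current RNG state.
#'
#' @param config a [fusionNetConfig()].
#' @return a [FusionNet-class] object.
#' @examples
#' net <- buildFusionNet(fusionNetConfig())
#' nSeqResBlocks(net)   # 37
#' @export
buildFusionNet <- function(config = fusionNetConfig()) {
  stopifnot(inherits(config, "FusionNetConfig"))
  plan <- config$stage_plan
  blocks <- pmax(1L, as.integer(round(plan$blocks * config$depth_scale)))
  layers <- list()
  cur <- plan$channels[1]
  layers[[length(layers) + 1L]] <-
    nnSeq(nnConv(3L, 3L, config$in_channels, cur), nnBN(cur), nnReLU())
  for (i in seq_len(nrow(plan))) {
    ch <- plan$channels[i]
    if (ch != cur) {
      layers[[length(layers) + 1L]] <-
        nnSeq(nnConv(1L, 1L, cur, ch), nnBN(ch), nnReLU())
      cur <- ch
    }
    for (b in seq_len(blocks[i]))
      layers[[length(layers) + 1L]] <- nnSeqRes(cur)
    if (plan$change[i] != "none")
      layers[[length(layers) + 1L]] <- nnUpDown(cur, plan$change[i])
  }
  layers[[length(layers) + 1L]] <- nnGAP()
  layers[[length(layers) + 1L]] <- nnLinear(cur, config$fc_dim)
  layers[[length(layers) + 1L]] <- nnReLU()
  layers[[length(layers) + 1L]] <- nnLinear(config$fc_dim, config$n_classes)
  net <- new("FusionNet", layers = layers, config = unclass(config),
             trained = FALSE, history = list())
  initializeWeights(net)
}

#' Initialize network weights
#'
#' All convolution and fully connected weights are drawn from a normal
#' distribution with mean 0 and variance `var` (default 0.01, i.e. sd 0.1);
#' biases are 0, batch-norm scale/shift start at 1/0 and running statistics
#' are reset.  Uses the current RNG state.
#'
#' @param net a [FusionNet-class].
#' @param var weight variance.
#' @return the re-initialized network.
#' @export
initializeWeights <- function(net, var = 0.01) {
  flat <- .modelParams(net@layers)
  for (nm in names(flat)) {
    leaf <- sub(".*\\.", "", nm)
    flat[[nm]] <- switch(leaf,
      w = array(rnorm(length(flat[[nm]]), 0, sqrt(var)), dim(flat[[nm]]) %||%
                  length(flat[[nm]])),
      b = rep(0, length(flat[[nm]])),
      gamma = rep(1, length(flat[[nm]])),
      beta = rep(0, length(flat[[nm]])),
      flat[[nm]])
  }
  net@layers <- .modelAssign(net@layers, flat)
  net@trained <- FALSE
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# forward through the body; features are the input to the final classifier
.netForward <- function(net, x, training = FALSE) {
  layers <- net@layers
  nL <- length(layers)
  caches <- vector("list", nL)
  feats <- NULL
  for (i in seq_len(nL)) {
    if (i == nL) feats <- x
    r <- nnForward(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  net@layers <- layers
  list(logits = x, features = feats, caches = caches, net = net)
}

.netBackward <- function(net, caches, dlogits) {
  nL <- length(net@layers)
  grads <- vector("list", nL)
  dy <- dlogits
  for (i in rev(seq_len(nL))) {
    r <- nnBackward(net@layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULLs as elements
  }
  list(grads = grads, dx = dy)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its logit gradient; labels are 0-based class ids
.crossEntropy <- function(logits, labels) {
  p <- .softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}

#' Gradients of the training loss for one batch
#'
#' Diagnostic entry point: runs one forward/backward pass in training mode
#' and returns the cross-entropy loss and a named flat list of per-parameter
#' gradients.
#'
#' @param net a [FusionNet-class].
#' @param x input batch `(H, W, C, N)`.
#' @param labels integer 0/1 labels, length N.
#' @return list with `loss` and `grads` (named list aligned with
#'   the model's flattened parameters).
#' @export
networkGradients <- function(net, x, labels) {
  fw <- .netForward(net, x, training = TRUE)
  ce <- .crossEntropy(fw$logits, as.integer(labels))
  bw <- .netBackward(fw$net, fw$caches, ce$dlogits)
  list(loss = ce$loss, grads = .modelGrads(fw$net@layers, bw$grads))
}

#' Training configuration
#'
#' Adam with learning rate 1e-4, at most 150 epochs, weights initialized from
#' N(0, 0.01), zero biases, cross-entropy loss; early stopping on a
#' validation-loss plateau with patience 15 when a validation fraction is
#' set.
#'
#' @param lr learning rate (default 1e-4).
#' @param max_epochs epoch cap (default 150).
#' @param batch_size minibatch size (default 10).
#' @param seed RNG seed controlling initialization and shuffling.
#' @param init_var weight-initialization variance (default 0.01).
#' @param val_fraction fraction held out for early stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @return list of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr = 1e-4, max_epochs = 150L, batch_size = 10L,
                        seed = 1L, init_var = 0.01, val_fraction = 0,
                        patience = 15L) {
  if (lr <= 0) stop("lr must be positive")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init_var = init_var, val_fraction = val_fraction,
                 patience = as.integer(patience)),
            class = "TrainConfig")
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a FusionNet
#'
#' Minibatch Adam training with cross-entropy loss.  The seed controls weight
#' initialization and shuffling, so a fixed seed reproduces the loss curve
#' exactly.  Requires both classes in `labels`.
#'
#' @param net a [FusionNet-class].
#' @param x input array `(H, W, C, N)` (see `stackSamples`-style layout) or a
#'   list of [VolumeSample-class] objects.
#' @param labels integer 0/1 labels (ignored when `x` is a sample list).
#' @param config a [trainConfig()].
#' @return the trained [FusionNet-class]; `@history` holds per-epoch `loss`
#'   and `accuracy` (and validation loss when early stopping is active).
#' @export
trainFusionNet <- function(net, x, labels = NULL, config = trainConfig()) {
  if (is.list(x) && !is.array(x)) {
    labels <- sampleLabels(x)
    x <- stackSamples(x)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training requires samples from both classes")
  N <- dim(x)[4]
  withSeed(config$seed, {
    net <- initializeWeights(net, config$init_var)
    val_idx <- integer(0)
    if (config$val_fraction > 0) {
      nv <- max(2L, round(N * config$val_fraction))
      val_idx <- sample.int(N, nv)
    }
    tr_idx <- setdiff(seq_len(N), val_idx)
    params <- .modelParams(net@layers)
    state <- list(t = 0,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    hist <- list(loss = numeric(0), accuracy = numeric(0),
                 val_loss = numeric(0))
    best_val <- Inf; stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      ep_loss <- 0; ep_hits <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        xb <- x[, , , b, drop = FALSE]
        yb <- labels[b]
        fw <- .netForward(net, xb, training = TRUE)
        net <- fw$net
        ce <- .crossEntropy(fw$logits, yb)
        bw <- .netBackward(net, fw$caches, ce$dlogits)
        grads <- .modelGrads(net@layers, bw$grads)
        upd <- .adamStep(params, grads, state, config$lr)
        params <- upd$params
        state <- upd$state
        net@layers <- .modelAssign(net@layers, params)
        ep_loss <- ep_loss + ce$loss * length(b)
        ep_hits <- ep_hits + sum(max.col(fw$logits, ties.method = "first") - 1L == yb)
      }
      hist$loss <- c(hist$loss, ep_loss / length(ord))
      hist$accuracy <- c(hist$accuracy, ep_hits / length(ord))
      if (length(val_idx)) {
        fv <- .netForward(net, x[, , , val_idx, drop = FALSE],
                          training = FALSE)
        vl <- .crossEntropy(fv$logits, labels[val_idx])$loss
        hist$val_loss <- c(hist$val_loss, vl)
        if (vl < best_val - 1e-6) { best_val <- vl; stall <- 0L }
        else stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    net@trained <- TRUE
    net@history <- hist
    net
  })
}

#' Extract deep features
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics)
#' and returns the penultimate fully connected activations.  Using an
#' untrained network is allowed but reported with a warning.
#'
#' @param net a [FusionNet-class].
#' @param x input array `(H, W, C, N)` or list of [VolumeSample-class]s.
#' @param batch_size forward batch size.
#' @return numeric matrix `N x fc_dim`.
#' @export
extractDeepFeatures <- function(net, x, batch_size = 16L) {
  if (is.list(x) && !is.array(x)) x <- stackSamples(x)
  if (!net@trained) warning("extracting features from an untrained network")
  N <- dim(x)[4]
  out <- NULL
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    fw <- .netForward(net, x[, , , b, drop = FALSE], training = FALSE)
    if (is.null(out)) out <- matrix(0, N, ncol(fw$features))
    out[b, ] <- fw$features
  }
  out
}

#' Predict class labels with a FusionNet
#'
#' @param net a trained [FusionNet-class].
#' @param x input array or sample list.
#' @return integer vector of 0/1 predictions.
#' @export
predictFusionNet <- function(net, x) {
  if (is.list(x) && !is.array(x)) x <- stackSamples(x)
  fw <- .netForward(net, x, training = FALSE)
  max.col(fw$logits, ties.method = "first") - 1L
}
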