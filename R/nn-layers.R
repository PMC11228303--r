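# Internal layer framework for the FusionNet implementation.
#
# A layer is a plain list: list(type, params = list(...), cfg = list(...),
# sub = list(<named sublayers>)).  Feature maps are (H, W, C, N) arrays;
# weights are (kh, kw, Cin, Cout).  Forward passes return the output, a
# cache for the backward pass and the (possibly updated, e.g. batch-norm
# running statistics) layer.  Backward passes return the input gradient and
# a gradient structure mirroring the layer's params/sub tree, so parameters
# and gradients flatten in the same canonical order.
#
# Transpose convolution is realized through the adjoint identities of the
# im2col convolution: its forward pass is the convolution's backward-data
# pass and vice versa.

.convPad <- function(k) as.integer((k - 1L) %/% 2L)

nnConv <- function(kh, kw, cin, cout, stride = 1L) {
  list(type = "conv",
       params = list(w = array(0, c(kh, kw, cin, cout))),
       cfg = list(stride = as.integer(stride),
                  ph = .convPad(kh), pw = .convPad(kw)),
       sub = NULL)
}

# transpose conv doubling spatial dims: kernel 4, stride 2, pad 1.
# Weight is stored as the weight of the adjoint (down) convolution:
# (kh, kw, C_out_of_tconv, C_in_of_tconv).
nnTconv <- function(cin, cout, k = 4L, stride = 2L) {
  list(type = "tconv",
       params = list(w = array(0, c(k, k, cout, cin))),
       cfg = list(stride = as.integer(stride), ph = 1L, pw = 1L),
       sub = NULL)
}

# depthwise factorized conv: one (kh x kw) filter per channel
nnDWConv <- function(kh, kw, C) {
  list(type = "dwconv",
       params = list(w = array(0, c(kh, kw, 1L, C))),
       cfg = list(stride = 1L, ph = .convPad(kh), pw = .convPad(kw)),
       sub = NULL)
}

nnBN <- function(C, momentum = 0.1, eps = 1e-5) {
  list(type = "bn",
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       cfg = list(momentum = momentum, eps = eps,
                  rmean = rep(0, C), rvar = rep(1, C)),
       sub = NULL)
}

nnReLU <- function() list(type = "relu", params = NULL, cfg = NULL, sub = NULL)

nnGAP <- function() list(type = "gap", params = NULL, cfg = NULL, sub = NULL)

nnLinear <- function(din, dout) {
  list(type = "linear",
       params = list(w = matrix(0, din, dout), b = rep(0, dout)),
       cfg = NULL, sub = NULL)
}

nnSeq <- function(...) {
  sub <- list(...)
  if (length(sub) == 1L && is.null(sub[[1]]$type) && is.null(names(sub)))
    sub <- sub[[1]]
  names(sub) <- sprintf("s%02d", seq_along(sub))
  list(type = "seq", params = NULL, cfg = NULL, sub = sub)
}

# (H*W*N) x C view of a feature map, and its inverse
.bnMat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}
.bnUnmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

.catChannels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  out
}

nnForward <- function(layer, x, training = TRUE) {
  switch(layer$type,
    conv = {
      y <- .cpp_conv_fwd(x, layer$params$w, layer$cfg$stride,
                         layer$cfg$ph, layer$cfg$pw)
      list(y = y, cache = list(x = x), layer = layer)
    },
    tconv = {
      d <- dim(x)
      Hout <- d[1] * layer$cfg$stride
      Wout <- d[2] * layer$cfg$stride
      y <- .cpp_conv_bwd_data(x, layer$params$w, layer$cfg$stride,
                              layer$cfg$ph, layer$cfg$pw, Hout, Wout)
      list(y = y, cache = list(x = x), layer = layer)
    },
    dwconv = {
      d <- dim(x)
      C <- d[3]
      y <- NULL
      caches <- vector("list", C)
      for (ch in seq_len(C)) {
        xc <- x[, , ch, , drop = FALSE]
        wc <- layer$params$w[, , , ch, drop = FALSE]
        yc <- .cpp_conv_fwd(xc, wc, layer$cfg$stride, layer$cfg$ph,
                            layer$cfg$pw)
        if (is.null(y)) y <- array(0, c(dim(yc)[1:2], C, d[4]))
        y[, , ch, ] <- yc
      }
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      m <- .bnMat(x)
      if (training) {
        mu <- colMeans(m)
        vv <- colMeans(m^2) - mu^2
        mom <- layer$cfg$momentum
        layer$cfg$rmean <- (1 - mom) * layer$cfg$rmean + mom * mu
        layer$cfg$rvar <- (1 - mom) * layer$cfg$rvar + mom * vv
      } else {
        mu <- layer$cfg$rmean
        vv <- layer$cfg$rvar
      }
      invstd <- 1 / sqrt(vv + layer$cfg$eps)
      xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
      ym <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                  layer$params$beta, "+")
      list(y = .bnUnmat(ym, d),
           cache = list(xhat = xhat, invstd = invstd, d = d,
                        training = training),
           layer = layer)
    },
    relu = list(y = pmax(x, 0), cache = list(pos = x > 0), layer = layer),
    gap = {
      d <- dim(x)
      cm <- colMeans(matrix(x, d[1] * d[2]))
      list(y = t(matrix(cm, d[3], d[4])), cache = list(d = d), layer = layer)
    },
    linear = {
      y <- sweep(x %*% layer$params$w, 2, layer$params$b, "+")
      list(y = y, cache = list(x = x), layer = layer)
    },
    seq = {
      caches <- vector("list", length(layer$sub))
      for (i in seq_along(layer$sub)) {
        r <- nnForward(layer$sub[[i]], x, training)
        x <- r$y
        caches[[i]] <- r$cache
        layer$sub[[i]] <- r$layer
      }
      list(y = x, cache = caches, layer = layer)
    },
    seqres = .seqresForward(layer, x, training),
    updown = .updownForward(layer, x, training),
    stop("unknown layer type: ", layer$type))
}

nnBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      d <- dim(cache$x)
      wd <- dim(layer$params$w)
      dw <- .cpp_conv_bwd_weight(cache$x, dy, layer$cfg$stride, layer$cfg$ph,
                                 layer$cfg$pw, wd[1], wd[2])
      dx <- .cpp_conv_bwd_data(dy, layer$params$w, layer$cfg$stride,
                               layer$cfg$ph, layer$cfg$pw, d[1], d[2])
      list(dx = dx, grads = list(params = list(w = dw)))
    },
    tconv = {
      wd <- dim(layer$params$w)
      dx <- .cpp_conv_fwd(dy, layer$params$w, layer$cfg$stride,
                          layer$cfg$ph, layer$cfg$pw)
      dw <- .cpp_conv_bwd_weight(dy, cache$x, layer$cfg$stride, layer$cfg$ph,
                                 layer$cfg$pw, wd[1], wd[2])
      list(dx = dx, grads = list(params = list(w = dw)))
    },
    dwconv = {
      d <- dim(cache$x)
      C <- d[3]
      wd <- dim(layer$params$w)
      dx <- array(0, d)
      dw <- array(0, wd)
      for (ch in seq_len(C)) {
        dyc <- dy[, , ch, , drop = FALSE]
        xc <- cache$x[, , ch, , drop = FALSE]
        wc <- layer$params$w[, , , ch, drop = FALSE]
        dw[, , , ch] <- .cpp_conv_bwd_weight(xc, dyc, layer$cfg$stride,
                                             layer$cfg$ph, layer$cfg$pw,
                                             wd[1], wd[2])
        dx[, , ch, ] <- .cpp_conv_bwd_data(dyc, wc, layer$cfg$stride,
                                           layer$cfg$ph, layer$cfg$pw,
                                           d[1], d[2])
      }
      list(dx = dx, grads = list(params = list(w = dw)))
    },
    bn = {
      d <- cache$d
      dym <- .bnMat(dy)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, layer$params$gamma, "*")
      if (cache$training) {
        n <- nrow(dym)
        t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
        dxm <- sweep(t1 - t2, 2, cache$invstd, "*")
      } else {
        dxm <- sweep(dxhat, 2, cache$invstd, "*")
      }
      list(dx = .bnUnmat(dxm, d),
           grads = list(params = list(gamma = dgamma, beta = dbeta)))
    },
    relu = list(dx = dy * cache$pos, grads = NULL),
    gap = {
      d <- cache$d
      scale <- 1 / (d[1] * d[2])
      dx <- array(rep(as.vector(t(dy)) * scale, each = d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    linear = {
      list(dx = dy %*% t(layer$params$w),
           grads = list(params = list(w = t(cache$x) %*% dy,
                                      b = colSums(dy))))
    },
    seq = {
      grads <- vector("list", length(layer$sub))
      for (i in rev(seq_along(layer$sub))) {
        r <- nnBackward(layer$sub[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[i] <- list(r$grads)   # keep NULLs as elements
      }
      names(grads) <- names(layer$sub)
      list(dx = dy, grads = list(sub = grads))
    },
    seqres = .seqresBackward(layer, cache, dy),
    updown = .updownBackward(layer, cache, dy),
    stop("unknown layer type: ", layer$type))
}

# ------------------------------------------------------ Seq-ResNet block -----

# One factorized 3x3 stage: 3x1 then 1x3 (plain), batch norm, ReLU.
.factStage <- function(C) {
  nnSeq(nnConv(3L, 1L, C, C), nnConv(1L, 3L, C, C), nnBN(C), nnReLU())
}

# Depthwise-separable factorized stage: depthwise 3x1 and 1x3, pointwise 1x1.
.dwFactStage <- function(C) {
  nnSeq(nnDWConv(3L, 1L, C), nnDWConv(1L, 3L, C), nnConv(1L, 1L, C, C),
        nnBN(C), nnReLU())
}

#' @noRd
# Seq-ResNet block: 1x1 reduce to `reduced` channels, split into `nsub`
# subspaces; subspace j undergoes j factorized 3x3 stages (j = 0 passes
# through untouched; the deeper subspaces use depthwise-separable stages);
# concatenate, 1x1 restore, add the identity shortcut.
nnSeqRes <- function(C, reduced = 15L, nsub = 5L) {
  if (reduced %% nsub != 0L) stop("reduced channels must divide into subspaces")
  cps <- reduced %/% nsub
  branches <- lapply(seq_len(nsub) - 1L, function(j) {
    if (j == 0L) return(nnSeq(list()))   # processed-free pass-through
    stages <- lapply(seq_len(j), function(s) {
      if (j == 1L) .factStage(cps) else .dwFactStage(cps)
    })
    nnSeq(stages)
  })
  names(branches) <- sprintf("b%d", seq_len(nsub) - 1L)
  sub <- c(list(reduce = nnSeq(nnConv(1L, 1L, C, reduced), nnBN(reduced),
                               nnReLU()),
                restore = nnSeq(nnConv(1L, 1L, reduced, C), nnBN(C))),
           branches)
  list(type = "seqres", params = NULL,
       cfg = list(C = C, reduced = reduced, nsub = nsub, cps = cps),
       sub = sub)
}

.seqresForward <- function(layer, x, training) {
  cfg <- layer$cfg
  r1 <- nnForward(layer$sub$reduce, x, training)
  layer$sub$reduce <- r1$layer
  h <- r1$y
  outs <- vector("list", cfg$nsub)
  bcaches <- vector("list", cfg$nsub)
  for (j in seq_len(cfg$nsub)) {
    idx <- (j - 1L) * cfg$cps + seq_len(cfg$cps)
    bn <- sprintf("b%d", j - 1L)
    rb <- nnForward(layer$sub[[bn]], h[, , idx, , drop = FALSE], training)
    layer$sub[[bn]] <- rb$layer
    outs[[j]] <- rb$y
    bcaches[[j]] <- rb$cache
  }
  cat <- .catChannels(outs)
  r2 <- nnForward(layer$sub$restore, cat, training)
  layer$sub$restore <- r2$layer
  list(y = x + r2$y,
       cache = list(reduce = r1$cache, branches = bcaches, restore = r2$cache),
       layer = layer)
}

.seqresBackward <- function(layer, cache, dy) {
  cfg <- layer$cfg
  rr <- nnBackward(layer$sub$restore, cache$restore, dy)
  dcat <- rr$dx
  dh <- NULL
  bgrads <- vector("list", cfg$nsub)
  for (j in seq_len(cfg$nsub)) {
    idx <- (j - 1L) * cfg$cps + seq_len(cfg$cps)
    rb <- nnBackward(layer$sub[[sprintf("b%d", j - 1L)]],
                     cache$branches[[j]], dcat[, , idx, , drop = FALSE])
    if (is.null(dh)) dh <- array(0, c(dim(rb$dx)[1:2], cfg$reduced,
                                      dim(rb$dx)[4]))
    dh[, , idx, ] <- rb$dx
    bgrads[[j]] <- rb$grads
  }
  rd <- nnBackward(layer$sub$reduce, cache$reduce, dh)
  grads <- c(list(reduce = rd$grads, restore = rr$grads),
             setNames(bgrads, sprintf("b%d", seq_len(cfg$nsub) - 1L)))
  list(dx = dy + rd$dx, grads = list(sub = grads))
}

# -------------------------------------------- up/down back-projection --------

#' @noRd
# Back-projection scale-change module.  mode "up": main = transpose conv
# (doubles), proj = strided conv back down, resid = transpose conv of the
# low-res residual; mode "down" mirrors it.  Output = 1x1 merge of the main
# path and the residual path; channels preserved.
nnUpDown <- function(C, mode = c("up", "down")) {
  mode <- match.arg(mode)
  if (mode == "up") {
    main <- nnSeq(nnTconv(C, C), nnBN(C), nnReLU())
    proj <- nnSeq(nnConv(3L, 3L, C, C, stride = 2L), nnBN(C), nnReLU())
    resid <- nnSeq(nnTconv(C, C))
  } else {
    main <- nnSeq(nnConv(3L, 3L, C, C, stride = 2L), nnBN(C), nnReLU())
    proj <- nnSeq(nnTconv(C, C), nnBN(C), nnReLU())
    resid <- nnSeq(nnConv(3L, 3L, C, C, stride = 2L))
  }
  list(type = "updown", params = NULL, cfg = list(C = C, mode = mode),
       sub = list(main = main, proj = proj, resid = resid,
                  merge = nnSeq(nnConv(1L, 1L, 2L * C, C))))
}

.updownForward <- function(layer, x, training) {
  if (layer$cfg$mode == "down" && any(dim(x)[1:2] %% 2L != 0L))
    stop("downsampling requires even spatial dimensions")
  r1 <- nnForward(layer$sub$main, x, training); layer$sub$main <- r1$layer
  r2 <- nnForward(layer$sub$proj, r1$y, training); layer$sub$proj <- r2$layer
  dfe <- r2$y - x
  r3 <- nnForward(layer$sub$resid, dfe, training); layer$sub$resid <- r3$layer
  r4 <- nnForward(layer$sub$merge, .catChannels(list(r1$y, r3$y)), training)
  layer$sub$merge <- r4$layer
  list(y = r4$y,
       cache = list(main = r1$cache, proj = r2$cache, resid = r3$cache,
                    merge = r4$cache, C = layer$cfg$C),
       layer = layer)
}

.updownBackward <- function(layer, cache, dy) {
  C <- cache$C
  rm4 <- nnBackward(layer$sub$merge, cache$merge, dy)
  dmain1 <- rm4$dx[, , seq_len(C), , drop = FALSE]
  dresid <- rm4$dx[, , C + seq_len(C), , drop = FALSE]
  rm3 <- nnBackward(layer$sub$resid, cache$resid, dresid)
  ddfe <- rm3$dx
  rm2 <- nnBackward(layer$sub$proj, cache$proj, ddfe)
  rm1 <- nnBackward(layer$sub$main, cache$main, dmain1 + rm2$dx)
  list(dx = rm1$dx - ddfe,
       grads = list(sub = list(main = rm1$grads, proj = rm2$grads,
                               resid = rm3$grads, merge = rm4$grads)))
}

# ------------------------------------------------- parameter bookkeeping -----

# flatten params (or a mirrored grads tree) into a named list, depth-first
.flattenParams <- function(node, prefix = "") {
  out <- list()
  if (is.null(node)) return(out)
  if (!is.null(node$params)) {
    for (pn in names(node$params))
      out[[paste0(prefix, pn)]] <- node$params[[pn]]
  }
  subs <- node$sub
  if (!is.null(subs)) {
    nms <- names(subs)
    for (i in seq_along(subs)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, .flattenParams(subs[[i]], paste0(prefix, nm, ".")))
    }
  }
  out
}

# layers: a list of top-level layers (a model body)
.modelParams <- function(layers) {
  out <- list()
  for (i in seq_along(layers))
    out <- c(out, .flattenParams(layers[[i]], paste0("L", i, ".")))
  out
}

.modelGrads <- function(layers, grads) {
  out <- list()
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) g <- list()
    # reuse the same walker: a grads tree mirrors params/sub
    out <- c(out, .flattenParams(g, paste0("L", i, ".")))
  }
  out
}

# write a flat named parameter list back into the layer tree (same order)
.assignParams <- function(node, flat, prefix = "") {
  if (!is.null(node$params)) {
    for (pn in names(node$params)) {
      key <- paste0(prefix, pn)
      v <- flat[[key]]
      old <- node$params[[pn]]
      node$params[[pn]] <- if (is.null(dim(old))) as.vector(v) else
        array(v, dim(old))
    }
  }
  subs <- node$sub
  if (!is.null(subs)) {
    nms <- names(subs)
    for (i in seq_along(subs)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      node$sub[[i]] <- .assignParams(subs[[i]], flat, paste0(prefix, nm, "."))
    }
  }
  node
}

.modelAssign <- function(layers, flat) {
  for (i in seq_along(layers))
    layers[[i]] <- .assignParams(layers[[i]], flat, paste0("L", i, "."))
  layers
}
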