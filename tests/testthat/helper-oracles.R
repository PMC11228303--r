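# Independent brute-force oracles used to cross-check the texture-matrix
# builders, filters and metrics.  These deliberately use naive enumeration,
# independent of the package's implementation paths.

# O(N^2)-style GLCM: enumerate every ordered voxel pair, count those at the
# requested displacement with both ends in the ROI.
oracleGLCM <- function(lev, roi, off, Ng, symmetric = TRUE) {
  d <- dim(lev)
  m <- matrix(0, Ng, Ng)
  coords <- arrayInd(seq_along(lev), d)
  for (v in which(roi & lev > 0)) {
    p <- coords[v, ]
    q <- p + off
    if (any(q < 1) || any(q > d)) next
    qi <- sum((q - 1) * cumprod(c(1, d[-length(d)]))) + 1
    if (!roi[qi] || lev[qi] == 0) next
    m[lev[v], lev[qi]] <- m[lev[v], lev[qi]] + 1
  }
  if (symmetric) m <- m + t(m)
  m
}

# brute-force run scanner: walk every line of the image along the offset,
# counting maximal runs of equal positive level
oracleGLRLM <- function(lev, roi, off, Ng) {
  d <- dim(lev)
  lv <- lev
  lv[!roi] <- 0L
  coords <- arrayInd(seq_along(lev), d)
  # line starts: voxels whose predecessor (p - off) is outside the array
  runs <- list()
  for (v in seq_along(lev)) {
    p <- coords[v, ]
    prev <- p - off
    if (!(any(prev < 1) || any(prev > d))) next
    # walk the line
    vals <- integer()
    q <- p
    while (!(any(q < 1) || any(q > d))) {
      qi <- sum((q - 1) * cumprod(c(1, d[-length(d)]))) + 1
      vals <- c(vals, lv[qi])
      q <- q + off
    }
    r <- rle(vals)
    keep <- r$values > 0
    if (any(keep)) runs <- c(runs, list(cbind(r$values[keep], r$lengths[keep])))
  }
  allr <- do.call(rbind, runs)
  Lmax <- max(allr[, 2])
  m <- matrix(0, Ng, Lmax)
  for (i in seq_len(nrow(allr)))
    m[allr[i, 1], allr[i, 2]] <- m[allr[i, 1], allr[i, 2]] + 1
  m
}

# flood-fill zones with Chebyshev connectivity by repeated neighbor growth
oracleGLSZM <- function(lev, roi, Ng) {
  d <- dim(lev)
  lv <- lev
  lv[!roi] <- 0L
  seen <- array(FALSE, d)
  coords <- arrayInd(seq_along(lev), d)
  zones <- list()
  for (v in seq_along(lev)) {
    if (lv[v] == 0L || seen[v]) next
    val <- lv[v]
    members <- v
    seen[v] <- TRUE
    frontier <- v
    while (length(frontier)) {
      nxt <- integer()
      for (f in frontier) {
        p <- coords[f, ]
        # all Chebyshev neighbors
        deltas <- as.matrix(do.call(expand.grid, rep(list(-1:1), length(d))))
        for (r in seq_len(nrow(deltas))) {
          q <- p + deltas[r, ]
          if (all(q >= 1) && all(q <= d) && any(deltas[r, ] != 0)) {
            qi <- sum((q - 1) * cumprod(c(1, d[-length(d)]))) + 1
            if (!seen[qi] && lv[qi] == val) {
              seen[qi] <- TRUE
              nxt <- c(nxt, qi)
              members <- c(members, qi)
            }
          }
        }
      }
      frontier <- nxt
    }
    zones <- c(zones, list(c(val, length(members))))
  }
  zm <- do.call(rbind, zones)
  Smax <- max(zm[, 2])
  m <- matrix(0, Ng, Smax)
  for (i in seq_len(nrow(zm)))
    m[zm[i, 1], zm[i, 2]] <- m[zm[i, 1], zm[i, 2]] + 1
  m
}

# sliding-window median with reflect padding (edge repeated), brute force
oracleMedianFilter <- function(x, w) {
  H <- nrow(x); W <- ncol(x); r <- w %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  y <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, x[refl(i + di, H), refl(j + dj, W)])
    y[i, j] <- median(vals)
  }
  y
}

# exhaustive threshold enumeration for average precision: at each distinct
# score, compute precision and recall; integrate the precision envelope
oracleAP <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  rec <- prec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    rec[i] <- sum(pred & labels == 1) / P
    prec[i] <- sum(pred & labels == 1) / sum(pred)
  }
  env <- vapply(seq_along(ths), function(i) max(prec[rec >= rec[i]]),
                numeric(1))
  sum(diff(c(0, rec)) * env)
}

# AUC as the normalized Mann-Whitney U statistic with rank-averaged ties
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# small random quantized test image
randomQuantized <- function(H = 8, W = 8, Ng = 4, roi_frac = 1) {
  img <- matrix(runif(H * W), H, W)
  roi <- matrix(runif(H * W) < roi_frac, H, W)
  if (!any(roi)) roi[1, 1] <- TRUE
  quantizeImage(img, roi, Ng)
}

# tiny 2D phantom set for fast pipeline tests (always generates at least 2,
# the generator's minimum, and subsets)
smallPhantoms <- function(n = 20, sep = 1, seed = 1, shape = c(32, 32)) {
  ph <- generatePhantoms(phantomSpec(n_samples = max(n, 2), shape = shape,
                                     n_channels = 1, separability = sep,
                                     seed = seed))
  ph[seq_len(n)]
}
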