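# Hand-crafted radiomics features over a region of interest: first-order
# histogram statistics, absolute-gradient statistics, and the three texture
# matrix families (GLCM, GLRLM, GLSZM) with their classical feature sets.
#
# GLCM follows Haralick's co-occurrence definition, GLRLM Galloway's run
# lengths and GLSZM Thibault's size zones with Chebyshev (infinity-norm)
# connectivity.  Feature estimators for skewness and kurtosis use the
# adjusted Fisher-Pearson forms with the sample standard deviation.

#' Quantize an image to Ng gray levels over a region of interest
#'
#' Equal-width binning of the ROI intensity range `[min, max]` into `Ng`
#' levels (the maximum maps to `Ng`); voxels outside the ROI get level 0.  A
#' constant ROI maps to level 1 with a warning.  Binning the ROI range makes
#' the levels invariant to affine intensity transforms.
#'
#' @param image numeric array (2D or 3D, one channel).
#' @param roi logical array of the same dimensions; must be non-empty.
#' @param Ng number of gray levels, `>= 2` (default 32).
#' @return a [QuantizedImage-class].
#' @export
quantizeImage <- function(image, roi, Ng = 32L) {
  if (is.null(dim(image))) image <- as.matrix(image)
  if (is.null(dim(roi))) roi <- array(roi, dim(image))
  if (!any(roi)) stop("empty ROI")
  if (Ng < 2) stop("Ng must be >= 2")
  Ng <- as.integer(Ng)
  v <- image[roi]
  lev <- array(0L, dim(image))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant ROI: all voxels mapped to level 1")
    lev[roi] <- 1L
  } else {
    lev[roi] <- pmin(Ng, as.integer(floor((v - rng[1]) / diff(rng) * Ng)) + 1L)
  }
  new("QuantizedImage", levels = lev, Ng = Ng, roi = array(roi, dim(image)),
      original = array(as.numeric(image), dim(image)))
}

# adjusted Fisher-Pearson skewness; 0 (flagged upstream) when degenerate
.skewness <- function(x) {
  n <- length(x); s <- sd(x)
  if (n < 3 || !is.finite(s) || s == 0) return(NA_real_)
  z <- (x - mean(x)) / s
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

# adjusted excess kurtosis (sample-sd z-scores)
.kurtosis <- function(x) {
  n <- length(x); s <- sd(x)
  if (n < 4 || !is.finite(s) || s == 0) return(NA_real_)
  z <- (x - mean(x)) / s
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' First-order intensity features
#'
#' Mean, variance, min, max, 10th/50th/90th percentiles, histogram energy
#' (sum of squared bin probabilities), histogram entropy (base-2), skewness
#' and kurtosis.  Skewness and kurtosis use the adjusted Fisher-Pearson
#' estimators with sample standard deviation; on constant or too-short input
#' they are imputed 0 and flagged.
#'
#' @param values numeric vector of ROI intensities.
#' @param nbins number of histogram bins for energy/entropy (default 32).
#' @return a [RadiomicsVector-class] with 11 features.
#' @export
firstOrderFeatures <- function(values, nbins = 32L) {
  stopifnot(length(values) >= 1)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    p <- 1
  } else {
    bins <- pmin(nbins, floor((values - rng[1]) / diff(rng) * nbins) + 1L)
    p <- tabulate(bins, nbins) / length(values)
  }
  pnz <- p[p > 0]
  qs <- quantile(values, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  sk <- .skewness(values); ku <- .kurtosis(values)
  flagged <- character()
  if (is.na(sk)) { sk <- 0; flagged <- c(flagged, "skewness") }
  if (is.na(ku)) { ku <- 0; flagged <- c(flagged, "kurtosis") }
  vals <- c(mean = mean(values),
            variance = if (length(values) > 1) var(values) else 0,
            min = rng[1], max = rng[2],
            p10 = qs[1], p50 = qs[2], p90 = qs[3],
            energy = sum(p^2),
            entropy = -sum(pnz * log2(pnz)),
            skewness = sk, kurtosis = ku)
  new("RadiomicsVector", values = vals, flagged = flagged)
}

# gradient along one axis: central differences, one-sided at the ends
.axisGradient <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  if (n < 2) return(array(0, d))
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  g <- m
  if (n > 2) g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[n, ] <- m[n, ] - m[n - 1, ]
  aperm(array(g, dim(ap)), order(perm))
}

#' Absolute-gradient features over a region of interest
#'
#' Computes the gradient magnitude (central differences, one-sided at the
#' array ends) and returns its mean, variance, skewness and kurtosis over the
#' ROI, with the same estimators and degenerate-input policy as
#' [firstOrderFeatures()].
#'
#' @param image numeric array.
#' @param roi logical array of the same dimensions.
#' @return a [RadiomicsVector-class] with 4 features.
#' @export
gradientFeatures <- function(image, roi) {
  if (is.null(dim(image))) image <- as.matrix(image)
  if (is.null(dim(roi))) roi <- array(roi, dim(image))
  if (sum(roi) < 2) stop("ROI too small for gradient statistics")
  g2 <- Reduce(`+`, lapply(seq_along(dim(image)),
                           function(ax) .axisGradient(image, ax)^2))
  mag <- sqrt(g2)[roi]
  flagged <- character()
  sk <- .skewness(mag); ku <- .kurtosis(mag)
  if (is.na(sk)) { sk <- 0; flagged <- c(flagged, "grad_skewness") }
  if (is.na(ku)) { ku <- 0; flagged <- c(flagged, "grad_kurtosis") }
  vals <- c(grad_mean = mean(mag),
            grad_variance = if (length(mag) > 1) var(mag) else 0,
            grad_skewness = sk, grad_kurtosis = ku)
  new("RadiomicsVector", values = vals, flagged = flagged)
}

#' Direction offsets for texture matrices
#'
#' In 2D, distance-`d` offsets for angles 0, 45, 90 and 135 degrees; in 3D,
#' the 13 unique directions of the 26-neighborhood (one per +/- pair).
#'
#' @param ndim 2 or 3.
#' @param d displacement distance (GLCM; runs always use `d = 1`).
#' @return list of integer offset vectors `(dh, dw[, dz])`.
#' @export
textureOffsets <- function(ndim = 2L, d = 1L) {
  d <- as.integer(d)
  if (ndim == 2L) {
    return(list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d)))
  }
  offs <- list()
  for (dz in -1:1) for (dw in -1:1) for (dh in -1:1) {
    o <- c(dh, dw, dz)
    if (all(o == 0)) next
    if (o[which(o != 0)[1]] > 0)   # one representative per +/- pair
      offs <- c(offs, list(as.integer(o * d)))
  }
  offs
}

# ordered (level_src, level_tgt) pairs at a displacement, both ends in ROI
.levelPairs <- function(lev, roi, off) {
  d <- dim(lev); nd <- length(d)
  idx <- lapply(seq_len(nd), function(k) {
    o <- off[k]
    if (o >= 0) seq_len(max(d[k] - o, 0L)) else seq(1L - o, d[k])
  })
  if (any(vapply(idx, length, integer(1)) == 0L))
    return(matrix(integer(), 0, 2))
  idx2 <- lapply(seq_len(nd), function(k) idx[[k]] + off[k])
  src <- do.call(`[`, c(list(lev), idx, list(drop = FALSE)))
  tgt <- do.call(`[`, c(list(lev), idx2, list(drop = FALSE)))
  ok <- (src > 0L) & (tgt > 0L)
  cbind(src[ok], tgt[ok])
}

#' Gray level co-occurrence matrix (GLCM)
#'
#' Counts ordered pairs of ROI voxels at displacement `d` along the given
#' direction whose levels are `(i, j)`; in symmetric mode the transpose is
#' added so the matrix counts unordered pairs in both scan orders.
#'
#' @param q a [QuantizedImage-class].
#' @param d displacement distance (default 1).
#' @param offset integer direction offset (see [textureOffsets()]); the
#'   default is the 0-degree (horizontal) direction.
#' @param symmetric add the transpose (default `TRUE`).
#' @param normalize divide by the total pair count (default `TRUE`).
#' @return a [TextureMatrix-class] of kind `"GLCM"`, `Ng x Ng`.
#' @export
glcm <- function(q, d = 1L, offset = NULL, symmetric = TRUE, normalize = TRUE) {
  stopifnot(is(q, "QuantizedImage"))
  nd <- length(dim(q@levels))
  if (is.null(offset)) offset <- c(0L, as.integer(d), rep(0L, nd - 2L))
  pr <- .levelPairs(q@levels, q@roi, offset)
  if (nrow(pr) == 0) stop("no valid voxel pairs for this displacement")
  Ng <- q@Ng
  m <- matrix(tabulate((pr[, 1] - 1L) * Ng + pr[, 2], Ng * Ng), Ng, Ng,
              byrow = TRUE)
  if (symmetric) m <- m + t(m)
  if (normalize) m <- m / sum(m)
  new("TextureMatrix", kind = "GLCM", counts = m, distance = as.integer(d),
      offset = as.integer(offset), normalized = normalize)
}

.asMatrixList <- function(m) if (is(m, "TextureMatrix")) list(m) else m

#' Haralick features of a normalized GLCM
#'
#' Contrast `sum (i-j)^2 p(i,j)`, energy (angular second moment)
#' `sum p^2`, entropy `-sum p log2 p` and homogeneity (inverse difference
#' moment) `sum p / (1 + (i-j)^2)`.  Given a list of matrices (one per
#' direction), features are averaged over directions.
#'
#' @param m a normalized `"GLCM"` [TextureMatrix-class] or a list of them.
#' @return named numeric vector of 4 features.
#' @export
glcmFeatures <- function(m) {
  ms <- .asMatrixList(m)
  feats <- vapply(ms, function(tm) {
    stopifnot(is(tm, "TextureMatrix"), tm@kind == "GLCM")
    if (!tm@normalized) stop("GLCM features require a normalized matrix")
    p <- tm@counts
    i <- row(p); j <- col(p)
    pnz <- p[p > 0]
    c(glcm_contrast = sum((i - j)^2 * p),
      glcm_energy = sum(p^2),
      glcm_entropy = -sum(pnz * log2(pnz)),
      glcm_homogeneity = sum(p / (1 + (i - j)^2)))
  }, numeric(4))
  rowMeans(feats)
}

#' Gray level run length matrix (GLRLM)
#'
#' Counts maximal runs of equal level along a direction; entry `(i, L)` is
#' the number of runs of level `i` and length `L`.  Runs are truncated at ROI
#' boundaries (out-of-ROI voxels break runs and are not counted).
#'
#' @param q a [QuantizedImage-class].
#' @param offset integer direction offset with entries in `{-1, 0, 1}`.
#' @return a [TextureMatrix-class] of kind `"GLRLM"`, `Ng x Lmax`.
#' @export
glrlm <- function(q, offset = c(0L, 1L)) {
  stopifnot(is(q, "QuantizedImage"))
  lev <- q@levels
  d <- dim(lev); nd <- length(d)
  if (length(offset) != nd) stop("offset rank must match the image")
  coords <- arrayInd(seq_along(lev), d)
  k0 <- which(offset != 0L)[1]
  if (is.na(k0)) stop("offset must be non-zero")
  t <- if (offset[k0] > 0L) coords[, k0] else d[k0] - coords[, k0] + 1L
  key <- coords - (t - 1L) %*% t(as.integer(offset))
  keyid <- as.integer(factor(apply(key, 1, paste, collapse = ",")))
  ord <- order(keyid, t)
  v <- as.integer(lev)[ord]
  # encode line id into the value stream so rle never merges across lines;
  # background (level 0) breaks runs and is dropped afterwards
  w <- as.numeric(keyid[ord]) * (q@Ng + 1) + v
  r <- rle(w)
  levr <- as.integer(r$values %% (q@Ng + 1))
  keep <- levr > 0L
  lens <- r$lengths[keep]; levr <- levr[keep]
  Lmax <- max(lens, 1L)
  m <- matrix(0, q@Ng, Lmax)
  for (ii in seq_along(lens)) m[levr[ii], lens[ii]] <- m[levr[ii], lens[ii]] + 1
  new("TextureMatrix", kind = "GLRLM", counts = m, distance = 0L,
      offset = as.integer(offset), normalized = FALSE)
}

#' Run-length features of a GLRLM
#'
#' Short-run emphasis, long-run emphasis, gray-level non-uniformity,
#' run-length non-uniformity and run fraction (total runs / ROI voxels).
#' Given a list of matrices (one per direction), features are averaged.
#'
#' @param m a `"GLRLM"` [TextureMatrix-class] (counts) or a list of them.
#' @return named numeric vector of 5 features.
#' @export
glrlmFeatures <- function(m) {
  ms <- .asMatrixList(m)
  feats <- vapply(ms, function(tm) {
    stopifnot(is(tm, "TextureMatrix"), tm@kind == "GLRLM")
    cc <- tm@counts
    L <- col(cc)
    Nr <- sum(cc)
    nvox <- sum(cc * L)
    c(glrlm_sre = sum(cc / L^2) / Nr,
      glrlm_lre = sum(cc * L^2) / Nr,
      glrlm_gln = sum(rowSums(cc)^2) / Nr,
      glrlm_rln = sum(colSums(cc)^2) / Nr,
      glrlm_run_fraction = Nr / nvox)
  }, numeric(5))
  rowMeans(feats)
}

#' Gray level size zone matrix (GLSZM)
#'
#' Counts connected zones of equal level; entry `(i, S)` is the number of
#' zones of level `i` with size `S`.  Connectivity is the infinity norm
#' (8-connected in 2D, 26-connected in 3D); the matrix is direction-free.
#'
#' @param q a [QuantizedImage-class].
#' @return a [TextureMatrix-class] of kind `"GLSZM"`, `Ng x Smax`.
#' @export
glszm <- function(q) {
  stopifnot(is(q, "QuantizedImage"))
  lab <- .cpp_label_zones(q@levels)
  nz <- max(lab)
  if (nz == 0) stop("empty ROI")
  sizes <- tabulate(lab[lab > 0], nz)
  levz <- q@levels[match(seq_len(nz), lab)]
  Smax <- max(sizes)
  m <- matrix(0, q@Ng, Smax)
  for (z in seq_len(nz)) m[levz[z], sizes[z]] <- m[levz[z], sizes[z]] + 1
  new("TextureMatrix", kind = "GLSZM", counts = m, distance = 0L,
      offset = integer(), normalized = FALSE)
}

#' Size-zone features of a GLSZM
#'
#' Small-zone emphasis, large-zone emphasis, gray-level non-uniformity,
#' zone-size non-uniformity and zone percentage (zones / ROI voxels) —
#' the run-length feature set with run length replaced by zone size.
#'
#' @param m a `"GLSZM"` [TextureMatrix-class] (counts).
#' @return named numeric vector of 5 features.
#' @export
glszmFeatures <- function(m) {
  stopifnot(is(m, "TextureMatrix"), m@kind == "GLSZM")
  cc <- m@counts
  S <- col(cc)
  Nz <- sum(cc)
  nvox <- sum(cc * S)
  c(glszm_sze = sum(cc / S^2) / Nz,
    glszm_lze = sum(cc * S^2) / Nz,
    glszm_gln = sum(rowSums(cc)^2) / Nz,
    glszm_szn = sum(colSums(cc)^2) / Nz,
    glszm_zone_percentage = Nz / nvox)
}

#' Radiomics extraction configuration
#'
#' @param ng number of gray levels for quantization (default 32).
#' @param mode `"2d"` (per-slice extraction, averaged over slices with a
#'   non-empty ROI) or `"3d"` (full-volume matrices, 13 directions).
#' @param glcm_d GLCM displacement distance.
#' @return list of class `"RadiomicsConfig"`.
#' @export
radiomicsConfig <- function(ng = 32L, mode = c("2d", "3d"), glcm_d = 1L) {
  structure(list(ng = as.integer(ng), mode = match.arg(mode),
                 glcm_d = as.integer(glcm_d)),
            class = "RadiomicsConfig")
}

# all feature groups for one 2D (or, in 3d mode, 3D) plane + roi
.planeFeatures <- function(plane, roi, config) {
  fo <- firstOrderFeatures(plane[roi], nbins = config$ng)
  gr <- gradientFeatures(plane, roi)
  q <- suppressWarnings(quantizeImage(plane, roi, config$ng))
  offs <- textureOffsets(length(dim(plane)), config$glcm_d)
  roffs <- textureOffsets(length(dim(plane)), 1L)
  gl <- glcmFeatures(lapply(offs, function(o)
    glcm(q, d = config$glcm_d, offset = o)))
  rl <- glrlmFeatures(lapply(roffs, function(o) glrlm(q, o)))
  sz <- glszmFeatures(glszm(q))
  list(values = c(featureValues(fo), featureValues(gr), gl, rl, sz),
       flagged = c(flaggedFeatures(fo), flaggedFeatures(gr)))
}

#' Extract the full radiomics vector of a sample
#'
#' Concatenates, per channel, the first-order (11), gradient (4), GLCM (4),
#' GLRLM (5) and GLSZM (5) feature groups in a fixed order.  For 3D input in
#' `"2d"` mode, features are computed per axial slice with a non-empty ROI
#' and averaged.  Degenerate features are imputed 0 and flagged; names are
#' stable across runs.
#'
#' @param sample a [VolumeSample-class] with a non-empty lesion mask.
#' @param config a [radiomicsConfig()].
#' @return a [RadiomicsVector-class] of length `29 * n_channels`.
#' @export
extractRadiomics <- function(sample, config = radiomicsConfig()) {
  img <- sampleImage(sample)
  roi <- sampleMask(sample)
  if (!any(roi)) stop("radiomics extraction requires a non-empty ROI mask")
  d <- dim(img)
  nch <- d[1]
  allv <- c(); allf <- character()
  for (ch in seq_len(nch)) {
    plane <- if (length(d) == 3L) img[ch, , ] else img[ch, , , ]
    if (length(d) == 4L && config$mode == "2d") {
      zs <- which(apply(roi, 3, any))
      per <- lapply(zs, function(z) .planeFeatures(plane[, , z], roi[, , z],
                                                   config))
      vals <- rowMeans(vapply(per, function(p) p$values,
                              numeric(length(per[[1]]$values))))
      names(vals) <- names(per[[1]]$values)
      flg <- unique(unlist(lapply(per, function(p) p$flagged)))
      pf <- list(values = vals, flagged = flg)
    } else {
      pf <- .planeFeatures(plane, roi, config)
    }
    names(pf$values) <- paste0("ch", ch, "_", names(pf$values))
    allv <- c(allv, pf$values)
    if (length(pf$flagged))
      allf <- c(allf, paste0("ch", ch, "_", pf$flagged))
  }
  new("RadiomicsVector", values = allv, flagged = allf)
}

#' Radiomics feature table for a dataset
#'
#' @param samples list of [VolumeSample-class] objects.
#' @param config a [radiomicsConfig()].
#' @param ids optional sample ids (default `S0001`, ...).
#' @return data.frame with `sample_id`, one column per feature, and `label`.
#' @export
radiomicsTable <- function(samples, config = radiomicsConfig(), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(samples))
  rows <- lapply(samples, function(s) featureValues(extractRadiomics(s, config)))
  mat <- do.call(rbind, rows)
  df <- data.frame(sample_id = ids, mat, label = sampleLabels(samples),
                   check.names = FALSE)
  rownames(df) <- NULL
  df
}
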