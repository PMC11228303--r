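# Training-time augmentation: per-axis flips, Gaussian blur, brightness,
# zoom, Gaussian noise, contrast and a mask-biased crop, each applied with
# its configured probability.  All draws come from R's global RNG so a fixed
# seed reproduces the full augmentation stream.

#' Augmentation configuration
#'
#' Probabilities and parameter ranges of the seven training-time
#' augmentations.  Defaults: per-axis flips with p 0.5; Gaussian blur with
#' p 0.15 and sigma uniform in (0.5, 1.5); brightness scaling with p 0.15 and
#' factor in (0.7, 1.3); zoom with p 0.15 and magnification in (1.0, 1.4)
#' (central crop resized back, cubic for the image, nearest for masks);
#' additive zero-mean Gaussian noise with p 0.15 and variance uniform in
#' (0, 0.33), applied on the normalized intensity scale; contrast scaling
#' with p 0.15, factor in (0.65, 1.5), clipped to the original range; and a
#' biased crop to `crop_shape` that retains a lesion voxel with p 0.4.
#'
#' @param p_flip_per_axis,p_blur,p_brightness,p_zoom,p_noise,p_contrast,p_biased_crop_foreground
#'   application probabilities in `[0, 1]`.
#' @param blur_sigma_range,brightness_range,zoom_range,noise_var_range,contrast_range
#'   ordered `(low, high)` parameter ranges.
#' @param crop_shape output shape of the biased crop including the channel
#'   axis, e.g. `c(5, 128, 128, 128)` for BraTS-style 3D input or
#'   `c(C, 128, 128)` in 2D; `NULL` disables cropping in [augmentSample()].
#' @return list of class `"AugmentationSpec"`.
#' @export
augmentationSpec <- function(p_flip_per_axis = 0.5,
                             p_blur = 0.15, blur_sigma_range = c(0.5, 1.5),
                             p_brightness = 0.15, brightness_range = c(0.7, 1.3),
                             p_zoom = 0.15, zoom_range = c(1.0, 1.4),
                             p_noise = 0.15, noise_var_range = c(0, 0.33),
                             p_contrast = 0.15, contrast_range = c(0.65, 1.5),
                             crop_shape = NULL,
                             p_biased_crop_foreground = 0.4) {
  ps <- c(p_flip_per_axis, p_blur, p_brightness, p_zoom, p_noise, p_contrast,
          p_biased_crop_foreground)
  if (any(ps < 0 | ps > 1)) stop("probabilities must lie in [0, 1]")
  for (r in list(blur_sigma_range, brightness_range, zoom_range,
                 noise_var_range, contrast_range))
    if (r[1] > r[2]) stop("ranges must be ordered low <= high")
  structure(list(p_flip_per_axis = p_flip_per_axis,
                 p_blur = p_blur, blur_sigma_range = blur_sigma_range,
                 p_brightness = p_brightness, brightness_range = brightness_range,
                 p_zoom = p_zoom, zoom_range = zoom_range,
                 p_noise = p_noise, noise_var_range = noise_var_range,
                 p_contrast = p_contrast, contrast_range = contrast_range,
                 crop_shape = crop_shape,
                 p_biased_crop_foreground = p_biased_crop_foreground),
            class = "AugmentationSpec")
}

.flipAxis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

.newSample <- function(sample, image = sampleImage(sample),
                       mask = sampleMask(sample),
                       fg = sampleForeground(sample)) {
  new("VolumeSample", image = image, mask = array(mask, dim(mask)),
      foreground = array(fg, dim(fg)), label = sampleLabel(sample))
}

#' Randomly reverse each spatial axis
#'
#' Each spatial axis is reversed independently with probability
#' `p_flip_per_axis`; image, mask and foreground are flipped congruently.
#'
#' @param sample a [VolumeSample-class].
#' @param spec an [augmentationSpec()].
#' @return the (possibly) flipped sample.
#' @export
randomFlip <- function(sample, spec = augmentationSpec()) {
  img <- sampleImage(sample); mask <- sampleMask(sample)
  fg <- sampleForeground(sample)
  for (ax in seq_along(dim(mask))) {
    if (runif(1) < spec$p_flip_per_axis) {
      img <- .flipAxis(img, ax + 1L)
      mask <- .flipAxis(mask, ax)
      fg <- .flipAxis(fg, ax)
    }
  }
  .newSample(sample, img, mask, fg)
}

.perChannel <- function(img, fn) {
  d <- dim(img)
  for (ch in seq_len(d[1])) {
    if (length(d) == 3L) img[ch, , ] <- fn(img[ch, , ])
    else img[ch, , , ] <- fn(img[ch, , , ])
  }
  img
}

#' Random Gaussian blur of the image channels
#'
#' With probability `p_blur`, convolves every image channel (never the mask)
#' with a Gaussian whose sigma is drawn uniformly from `blur_sigma_range`.
#'
#' @inheritParams randomFlip
#' @export
randomGaussianBlur <- function(sample, spec = augmentationSpec()) {
  if (runif(1) >= spec$p_blur) return(sample)
  sigma <- runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
  .newSample(sample, .perChannel(sampleImage(sample),
                                 function(p) gaussBlurArray(p, sigma)))
}

#' Random brightness scaling
#'
#' With probability `p_brightness`, multiplies all voxels by a factor drawn
#' uniformly from `brightness_range` (zero background is unaffected by a
#' multiplicative change).
#'
#' @inheritParams randomFlip
#' @export
randomBrightness <- function(sample, spec = augmentationSpec()) {
  if (runif(1) >= spec$p_brightness) return(sample)
  f <- runif(1, spec$brightness_range[1], spec$brightness_range[2])
  .newSample(sample, sampleImage(sample) * f)
}

#' Random contrast scaling with range clipping
#'
#' With probability `p_contrast`, multiplies voxels by a factor from
#' `contrast_range` and clips the result to the pre-transform min/max so the
#' output never exceeds the original range.
#'
#' @inheritParams randomFlip
#' @export
randomContrast <- function(sample, spec = augmentationSpec()) {
  if (runif(1) >= spec$p_contrast) return(sample)
  f <- runif(1, spec$contrast_range[1], spec$contrast_range[2])
  img <- sampleImage(sample)
  img2 <- pmin(pmax(img * f, min(img)), max(img))
  .newSample(sample, array(img2, dim(img)))
}

#' Random additive Gaussian noise
#'
#' With probability `p_noise`, adds zero-mean Gaussian noise with variance
#' drawn uniformly from `noise_var_range` to the foreground voxels of every
#' channel (the zero background partition is preserved).
#'
#' @inheritParams randomFlip
#' @export
randomNoise <- function(sample, spec = augmentationSpec()) {
  if (runif(1) >= spec$p_noise) return(sample)
  v <- runif(1, spec$noise_var_range[1], spec$noise_var_range[2])
  img <- sampleImage(sample)
  fgv <- as.vector(sampleForeground(sample))
  flat <- matrix(img, nrow = dim(img)[1])
  nfg <- sum(fgv)
  for (ch in seq_len(nrow(flat)))
    flat[ch, fgv] <- flat[ch, fgv] + rnorm(nfg, 0, sqrt(v))
  .newSample(sample, array(flat, dim(img)))
}

#' Random zoom (central crop magnified back to the input shape)
#'
#' With probability `p_zoom`, crops the central `1/f` portion of the field of
#' view (`f` uniform in `zoom_range`) and resizes it back to the original
#' shape — cubic interpolation for image channels, nearest neighbor for mask
#' and foreground.  Output shape always equals input shape.  3D volumes are
#' zoomed in-plane, slice by slice.
#'
#' @inheritParams randomFlip
#' @export
randomZoom <- function(sample, spec = augmentationSpec()) {
  if (runif(1) >= spec$p_zoom) return(sample)
  f <- runif(1, spec$zoom_range[1], spec$zoom_range[2])
  if (f <= 1) return(sample)
  img <- sampleImage(sample); mask <- sampleMask(sample)
  fg <- sampleForeground(sample)
  sdim <- dim(mask)
  hw <- sdim[1:2]
  cs <- pmax(2L, as.integer(round(hw / f)))
  lo <- (hw - cs) %/% 2L + 1L
  hi <- lo + cs - 1L
  zoom2 <- function(m, method) {
    resizeMatrix(m[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE], hw, method)
  }
  if (length(sdim) == 2L) {
    img <- .perChannel(img, function(p) zoom2(p, "cubic"))
    mask <- zoom2(mask + 0, "nearest") > 0.5
    fg <- zoom2(fg + 0, "nearest") > 0.5
  } else {
    for (z in seq_len(sdim[3])) {
      for (ch in seq_len(dim(img)[1]))
        img[ch, , , z] <- zoom2(img[ch, , , z], "cubic")
      mask[, , z] <- zoom2(mask[, , z] + 0, "nearest") > 0.5
      fg[, , z] <- zoom2(fg[, , z] + 0, "nearest") > 0.5
    }
  }
  .newSample(sample, img, array(mask, sdim), array(fg, sdim))
}

#' Biased crop to a fixed patch shape
#'
#' Crops a patch of shape `crop_shape` (channels included).  With probability
#' `p_biased_crop_foreground` the window is forced to contain at least one
#' lesion-mask voxel: a mask voxel is drawn uniformly and the window is drawn
#' uniformly among windows containing it.  Otherwise the window is uniform
#' over all positions.  Inputs smaller than the patch are zero-padded first.
#'
#' @inheritParams randomFlip
#' @param crop_shape overrides `spec$crop_shape` when given.
#' @return a [VolumeSample-class] of shape `crop_shape`.
#' @export
biasedCrop <- function(sample, spec = augmentationSpec(), crop_shape = NULL) {
  cs <- if (!is.null(crop_shape)) crop_shape else spec$crop_shape
  if (is.null(cs)) stop("crop_shape must be given")
  img <- sampleImage(sample); mask <- sampleMask(sample)
  fg <- sampleForeground(sample)
  d <- dim(img)
  if (length(cs) != length(d)) stop("crop_shape rank must match the sample")
  if (cs[1] != d[1]) stop("crop_shape channel count must match the sample")
  sdim <- d[-1]; csp <- cs[-1]
  # zero-pad if any spatial dim is smaller than the patch
  if (any(sdim < csp)) {
    pad <- pmax(csp - sdim, 0L)
    nsd <- sdim + pad
    nimg <- array(0, c(d[1], nsd)); nmask <- array(FALSE, nsd)
    nfg <- array(FALSE, nsd)
    idx <- lapply(seq_along(sdim), function(k) seq_len(sdim[k]))
    nimg <- do.call(`[<-`, c(list(nimg), list(seq_len(d[1])), idx, list(img)))
    nmask <- do.call(`[<-`, c(list(nmask), idx, list(mask)))
    nfg <- do.call(`[<-`, c(list(nfg), idx, list(fg)))
    img <- nimg; mask <- nmask; fg <- nfg; sdim <- nsd
  }
  biased <- runif(1) < spec$p_biased_crop_foreground
  if (biased && !any(mask)) {
    warning("biased crop requested but mask is empty; falling back to uniform")
    biased <- FALSE
  }
  starts <- integer(length(sdim))
  if (biased) {
    vox <- which(mask)
    anchor <- arrayInd(vox[sample.int(length(vox), 1L)], dim(mask))
    for (k in seq_along(sdim)) {
      lo <- max(1L, anchor[k] - csp[k] + 1L)
      hi <- min(anchor[k], sdim[k] - csp[k] + 1L)
      starts[k] <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
  } else {
    for (k in seq_along(sdim)) {
      m <- sdim[k] - csp[k] + 1L
      starts[k] <- sample.int(m, 1L)
    }
  }
  idx <- lapply(seq_along(sdim), function(k) starts[k] + seq_len(csp[k]) - 1L)
  .newSample(sample,
             do.call(`[`, c(list(img), list(seq_len(d[1])), idx,
                            list(drop = FALSE))),
             array(do.call(`[`, c(list(mask), idx, list(drop = FALSE))), csp),
             array(do.call(`[`, c(list(fg), idx, list(drop = FALSE))), csp))
}

#' Apply the full augmentation chain
#'
#' Applies, in a fixed order: flips, Gaussian blur, brightness, zoom, noise,
#' contrast and (when `crop_shape` is set) the biased crop.  The label is
#' never altered; flips, zoom and crop transform image, mask and foreground
#' congruently.
#'
#' @inheritParams randomFlip
#' @export
augmentSample <- function(sample, spec = augmentationSpec()) {
  sample <- randomFlip(sample, spec)
  sample <- randomGaussianBlur(sample, spec)
  sample <- randomBrightness(sample, spec)
  sample <- randomZoom(sample, spec)
  sample <- randomNoise(sample, spec)
  sample <- randomContrast(sample, spec)
  if (!is.null(spec$crop_shape)) sample <- biasedCrop(sample, spec)
  sample
}
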