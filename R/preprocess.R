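# BraTS-style preprocessing: background cropping, per-channel z-scoring over
# the non-zero foreground, foreground one-hot channel, median / soft weighted
# median denoising, slice resizing.  Conventions: channel-first arrays,
# 0-valued background, a voxel is foreground iff any channel is non-zero
# before normalization.

#' Crop the zero background of a channel-first volume
#'
#' Removes border voxels that are zero in every channel, returning the minimal
#' bounding box and the crop offsets needed to re-embed it exactly.
#'
#' @param image channel-first numeric array, `(C, H, W)` or `(C, H, W, D)`.
#' @return list with `image` (cropped array), `offsets` (0-based offset per
#'   spatial axis) and `shape` (the original spatial shape).
#' @seealso [embedAtOffsets()] for the exact inverse.
#' @export
cropBackground <- function(image) {
  d <- dim(image)
  nz <- apply(image != 0, seq_along(d)[-1], any)
  if (!any(nz)) stop("empty volume: all voxels are zero")
  nd <- length(dim(nz))
  ranges <- lapply(seq_len(nd), function(k) {
    keep <- apply(nz, k, any)
    range(which(keep))
  })
  idx <- c(list(seq_len(d[1])), lapply(ranges, function(r) r[1]:r[2]))
  out <- do.call(`[`, c(list(image), idx, list(drop = FALSE)))
  list(image = out,
       offsets = vapply(ranges, function(r) r[1] - 1L, integer(1)),
       shape = d[-1])
}

#' Re-embed a cropped volume at its original offsets
#'
#' @param image cropped channel-first array.
#' @param offsets 0-based spatial offsets as returned by [cropBackground()].
#' @param shape original spatial shape.
#' @return channel-first array of the original shape, zero outside the crop.
#' @export
embedAtOffsets <- function(image, offsets, shape) {
  d <- dim(image)
  out <- array(0, c(d[1], shape))
  idx <- c(list(seq_len(d[1])),
           lapply(seq_along(shape), function(k) offsets[k] + seq_len(d[k + 1])))
  do.call(`[<-`, c(list(out), idx, list(image)))
}

#' Z-score each channel over its non-zero foreground
#'
#' The foreground is the set of voxels non-zero in any channel.  Each channel
#' is centered and scaled using the mean and sample standard deviation of its
#' foreground voxels only; background voxels are left exactly 0.  A channel
#' with a constant foreground gets a standard-deviation floor of `1e-8`, with
#' a warning.
#'
#' @param image channel-first numeric array.
#' @param mask optional lesion mask (spatial dims); stored on the result.
#' @param label optional class label (0/1); stored on the result.
#' @return a [VolumeSample-class] with normalized image and recorded
#'   foreground.
#' @export
znormalizeNonzero <- function(image, mask = NULL, label = 0L) {
  d <- dim(image)
  fg <- apply(image != 0, seq_along(d)[-1], any)
  if (!any(fg)) stop("empty volume: no foreground voxels")
  C <- d[1]
  flat <- matrix(image, nrow = C)      # channels x voxels
  fgv <- as.vector(fg)
  for (ch in seq_len(C)) {
    v <- flat[ch, fgv]
    s <- sd(v)
    if (!is.finite(s) || s < 1e-8) {
      warning("channel ", ch, ": constant foreground, sd floor applied")
      s <- 1e-8
    }
    flat[ch, fgv] <- (v - mean(v)) / s
  }
  out <- array(flat, d)
  if (is.null(mask)) mask <- array(FALSE, d[-1])
  new("VolumeSample", image = out, mask = mask, foreground = fg,
      label = as.integer(label))
}

#' Append a foreground one-hot channel
#'
#' Adds one channel that is 1 on the foreground (non-zero region recorded
#' before normalization) and 0 elsewhere, distinguishing normalized voxels
#' near zero from true background.
#'
#' @param sample a [VolumeSample-class] with foreground recorded.
#' @return a [VolumeSample-class] with `C + 1` channels.
#' @export
addForegroundChannel <- function(sample) {
  img <- sampleImage(sample)
  d <- dim(img)
  out <- array(0, c(d[1] + 1L, d[-1]))
  flat <- matrix(out, nrow = d[1] + 1L)
  flat[seq_len(d[1]), ] <- matrix(img, nrow = d[1])
  flat[d[1] + 1L, ] <- as.numeric(as.vector(sampleForeground(sample)))
  new("VolumeSample", image = array(flat, c(d[1] + 1L, d[-1])),
      mask = sampleMask(sample), foreground = sampleForeground(sample),
      label = sampleLabel(sample))
}

#' Filter configuration for denoising
#'
#' @param kind `"median"` or `"swmf"` (soft weighted median).
#' @param window odd window size `>= 3` (applied per axis).
#' @param swmf_temperature positive softness of the SWMF weights; the filter
#'   approaches the plain median as the temperature goes to 0.
#' @return list of class `"FilterConfig"`.
#' @export
filterConfig <- function(kind = c("median", "swmf"), window = 3L,
                         swmf_temperature = 1) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (kind == "swmf" && swmf_temperature <= 0)
    stop("swmf_temperature must be positive")
  structure(list(kind = kind, window = window,
                 swmf_temperature = swmf_temperature, padding = "reflect"),
            class = "FilterConfig")
}

#' Median filter for a 2D image
#'
#' Each output pixel is the median of its `window x window` neighborhood
#' under reflect padding.
#'
#' @param image numeric matrix.
#' @param cfg a [filterConfig()] with `kind = "median"`.
#' @return filtered matrix, same dimensions.
#' @export
medianFilterImage <- function(image, cfg = filterConfig("median")) {
  stopifnot(inherits(cfg, "FilterConfig"), cfg$kind == "median")
  .cpp_median_filter2(image, cfg$window, cfg$window)
}

#' Soft weighted median filter (SWMF) for a 2D image
#'
#' A weighted median over the reflect-padded window where each neighbor's
#' weight is `exp(-|v - median(window)| / temperature)` (a softmax of the
#' negative absolute deviation from the window median).  As the temperature
#' goes to 0 the weights concentrate on the window median and the filter
#' reduces to [medianFilterImage()]; larger temperatures average over
#' near-median values, softening the edge behavior of the hard median.
#'
#' @param image numeric matrix.
#' @param cfg a [filterConfig()] with `kind = "swmf"`.
#' @return filtered matrix, same dimensions.
#' @export
swmfFilterImage <- function(image, cfg = filterConfig("swmf")) {
  stopifnot(inherits(cfg, "FilterConfig"), cfg$kind == "swmf")
  .cpp_swmf_filter2(image, cfg$window, cfg$window, cfg$swmf_temperature)
}

#' Bilinear resize of a 2D slice
#'
#' @param image numeric matrix (one channel of one slice).
#' @param target integer length-2 target size, default `c(256, 256)`.
#' @return resized matrix; values stay within the input range up to
#'   interpolation rounding.
#' @export
resizeSlice <- function(image, target = c(256L, 256L)) {
  if (any(target < 1)) stop("target size must be positive")
  if (all(dim(image) == target)) return(image)
  resizeMatrix(image, target, "bilinear")
}

#' Full preprocessing chain for one volume
#'
#' Applies, in order: background crop, optional denoising filter (slice-wise
#' for 3D input), non-zero z-scoring and the foreground one-hot channel.
#'
#' @param image channel-first numeric array.
#' @param mask optional lesion mask matching the spatial dims.
#' @param label class label.
#' @param filter optional [filterConfig()]; `NULL` disables denoising.
#' @param resize optional in-plane target `(H, W)` applied after
#'   normalization (bilinear for image channels, nearest for mask and
#'   foreground), giving every sample the fixed grid the network expects.
#' @return list with `sample` (a [VolumeSample-class]) and `offsets`/`shape`
#'   from the crop for exact re-embedding.
#' @export
preprocessVolume <- function(image, mask = NULL, label = 0L, filter = NULL,
                             resize = NULL) {
  cr <- cropBackground(image)
  img <- cr$image
  if (!is.null(mask)) {
    idx <- lapply(seq_along(cr$offsets),
                  function(k) cr$offsets[k] + seq_len(dim(img)[k + 1]))
    mask <- do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
    mask <- array(mask, dim(img)[-1])
  }
  if (!is.null(filter)) {
    fn <- if (filter$kind == "median") medianFilterImage else swmfFilterImage
    d <- dim(img)
    for (ch in seq_len(d[1])) {
      if (length(d) == 3L) {
        img[ch, , ] <- fn(img[ch, , ], filter)
      } else {
        for (z in seq_len(d[4])) img[ch, , , z] <- fn(img[ch, , , z], filter)
      }
    }
  }
  sample <- znormalizeNonzero(img, mask = mask, label = label)
  sample <- addForegroundChannel(sample)
  if (!is.null(resize)) sample <- .resizeSample(sample, resize)
  list(sample = sample, offsets = cr$offsets, shape = cr$shape)
}

# in-plane resize of a whole sample: bilinear image, nearest mask/foreground
.resizeSample <- function(sample, target) {
  img <- sampleImage(sample); mask <- sampleMask(sample)
  fg <- sampleForeground(sample)
  d <- dim(img)
  nsd <- if (length(d) == 3L) as.integer(target) else
    c(as.integer(target), d[4])
  out <- array(0, c(d[1], nsd))
  if (length(d) == 3L) {
    for (ch in seq_len(d[1])) out[ch, , ] <- resizeMatrix(img[ch, , ], target)
    nmask <- resizeMatrix(mask + 0, target, "nearest") > 0.5
    nfg <- resizeMatrix(fg + 0, target, "nearest") > 0.5
  } else {
    nmask <- array(FALSE, nsd); nfg <- array(FALSE, nsd)
    for (z in seq_len(d[4])) {
      for (ch in seq_len(d[1]))
        out[ch, , , z] <- resizeMatrix(img[ch, , , z], target)
      nmask[, , z] <- resizeMatrix(mask[, , z] + 0, target, "nearest") > 0.5
      nfg[, , z] <- resizeMatrix(fg[, , z] + 0, target, "nearest") > 0.5
    }
  }
  new("VolumeSample", image = out, mask = array(nmask, nsd),
      foreground = array(nfg, nsd), label = sampleLabel(sample))
}
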