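# Synthetic texture-phantom generator.  Phantoms emulate the structure of a
# skull-stripped multi-modal MRI volume: a zero-valued background ring, a
# "tissue" foreground carrying a smooth Gaussian random field, and a lesion
# blob whose interior texture follows class-dependent parameters.  Class
# separability is controlled through the correlation length (Gaussian
# smoothing sigma) and lesion radius of the malignant class.

#' Specification of a phantom dataset
#'
#' Defines the study conditions for [generatePhantoms()]: sample count, shape,
#' channels, per-class texture parameters and the zero-background fraction.
#' Texture follows a Gaussian random field (white noise convolved with a
#' Gaussian kernel of class-specific sigma) mapped affinely to the requested
#' intensity mean/sd, so class differences act directly on the correlation
#' structure that co-occurrence statistics measure.
#'
#' @param n_samples number of phantoms (>= 2; both classes are represented).
#' @param shape spatial dimensions, length 2 (H, W) or 3 (H, W, D).
#' @param n_channels number of channels (default 4, BraTS-style modalities).
#' @param separability in `[0, 1]`; 0 gives identical class parameters
#'   (chance-level separation), 1 the default maximal texture gap.  Used only
#'   when `class_params` is `NULL`.
#' @param class_params optional list with elements `benign` and `malignant`,
#'   each a list of `sigma` (field correlation length, voxels), `mean`, `sd`
#'   (intensity affine map) and `radius_range` (lesion radius as a fraction of
#'   the smallest spatial dimension).
#' @param background_fraction minimum fraction of exactly-zero border voxels.
#' @param seed RNG seed; fixed seed gives a bit-identical dataset.
#' @return a list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(n_samples = 4L, shape = c(32L, 32L), n_channels = 1L,
                        separability = 1, class_params = NULL,
                        background_fraction = 0.1, seed = 1L) {
  if (n_samples < 2L) stop("n_samples must be at least 2")
  if (!length(shape) %in% c(2L, 3L) || any(shape < 8))
    stop("shape must be 2 or 3 dimensions, each >= 8")
  if (separability < 0 || separability > 1)
    stop("separability must be in [0, 1]")
  if (is.null(class_params)) {
    class_params <- list(
      benign    = list(sigma = 0.6, mean = 100, sd = 20,
                       radius_range = c(0.18, 0.28)),
      malignant = list(sigma = 0.6 + 2.4 * separability, mean = 100, sd = 20,
                       radius_range = c(0.18, 0.28) + 0.1 * separability))
  }
  structure(list(n_samples = as.integer(n_samples),
                 shape = as.integer(shape),
                 n_channels = as.integer(n_channels),
                 separability = separability,
                 class_params = class_params,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# smallest border width so that >= frac of voxels are zero
.borderWidth <- function(shape, frac) {
  if (frac <= 0) return(0L)
  for (b in 0:(min(shape) %/% 2 - 1)) {
    inner <- prod(pmax(shape - 2L * b, 0L))
    if (1 - inner / prod(shape) >= frac) return(b)
  }
  stop("background_fraction too large for this shape")
}

.randomField <- function(shape, sigma) {
  f <- array(rnorm(prod(shape)), shape)
  if (sigma > 0) f <- gaussBlurArray(f, sigma)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

.lesionMask <- function(shape, border, radius_range) {
  r <- runif(1, radius_range[1], radius_range[2]) * min(shape)
  lo <- rep(border + r + 1, length(shape))
  hi <- shape - border - r
  ctr <- vapply(seq_along(shape),
                function(k) runif(1, min(lo[k], hi[k]), max(lo[k], hi[k])),
                numeric(1))
  grids <- lapply(seq_along(shape), function(k) {
    g <- array(0, shape)
    idx <- slice.index(g, k)
    (idx - ctr[k])^2
  })
  d2 <- Reduce(`+`, grids)
  d2 <= r^2
}

#' Generate labeled texture phantoms
#'
#' Produces `n_samples` [VolumeSample-class] objects with alternating labels.
#' Every sample has a zero background ring, a textured tissue foreground and
#' a lesion blob (the ROI mask); the lesion interior texture and radius follow
#' the parameters of the sample's class.  Deterministic for a fixed seed.
#'
#' @param spec a [phantomSpec()].
#' @return list of [VolumeSample-class] objects; labels 0 (benign) and 1
#'   (malignant) alternate so both classes are always represented.
#' @examples
#' ph <- generatePhantoms(phantomSpec(n_samples = 4, shape = c(32, 32), seed = 7))
#' sampleLabel(ph[[2]])
#' @export
generatePhantoms <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  shape <- spec$shape
  border <- .borderWidth(shape, spec$background_fraction)
  withSeed(spec$seed, {
    lapply(seq_len(spec$n_samples), function(i) {
      label <- as.integer((i - 1L) %% 2L)   # alternate benign/malignant
      cp <- if (label == 1L) spec$class_params$malignant else
        spec$class_params$benign
      # foreground region: everything inside the zero border
      fg <- array(FALSE, shape)
      idx <- lapply(shape, function(n) (border + 1L):(n - border))
      fg <- do.call(`[<-`, c(list(fg), idx, list(TRUE)))
      mask <- .lesionMask(shape, border, cp$radius_range) & fg
      if (!any(mask))   # degenerate geometry: fall back to a central voxel
        mask <- do.call(`[<-`, c(list(mask), as.list(pmax(border + 1L, shape %/% 2L)),
                                 list(TRUE)))
      img <- array(0, c(spec$n_channels, shape))
      for (ch in seq_len(spec$n_channels)) {
        tissue <- .randomField(shape, 0.8) * 15 + 100
        lesion <- .randomField(shape, cp$sigma) * cp$sd + cp$mean
        plane <- tissue
        plane[mask] <- lesion[mask]
        plane[!fg] <- 0
        plane[fg & plane == 0] <- 1e-8   # foreground must stay non-zero
        if (length(shape) == 2L) img[ch, , ] <- plane else img[ch, , , ] <- plane
      }
      new("VolumeSample", image = img, mask = mask,
          foreground = fg, label = label)
    })
  })
}

#' Write a 3D phantom to NIfTI
#'
#' Writes one file per channel with suffixes `_000` ... (BraTS-style dialect),
#' or a single 4D file with `dialect = "4d"` (channels on the last axis).
#' Writing goes through a temporary file and a rename, so a failed write
#' leaves no partial file.
#'
#' @param sample a 3D [VolumeSample-class].
#' @param path output path prefix (per-channel mode) or filename (4D mode);
#'   `.nii.gz` is appended when absent.
#' @param dialect `"channels"` (default, one file per channel) or `"4d"`.
#' @return invisibly, the written file path(s).
#' @export
writePhantomNifti <- function(sample, path, dialect = c("channels", "4d")) {
  dialect <- match.arg(dialect)
  img <- sampleImage(sample)
  if (length(dim(img)) != 4)
    stop("unsupported dimensionality: NIfTI export requires a 3D sample")
  .safeWrite <- function(arr, file) {
    if (!dir.exists(dirname(file)))
      stop("cannot write NIfTI: directory does not exist: ", dirname(file))
    tmp <- tempfile(tmpdir = dirname(file), fileext = ".nii.gz")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), tmp)
    if (!file.rename(tmp, file)) stop("cannot write NIfTI file: ", file)
    file
  }
  if (dialect == "4d") {
    file <- if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii.gz")
    arr <- aperm(img, c(2, 3, 4, 1))      # channels last
    return(invisible(.safeWrite(arr, file)))
  }
  files <- vapply(seq_len(dim(img)[1]), function(ch) {
    file <- sprintf("%s_%03d.nii.gz", sub("\\.nii(\\.gz)?$", "", path), ch - 1L)
    .safeWrite(img[ch, , , ], file)
  }, character(1))
  invisible(files)
}

#' Write a CSV manifest for a phantom dataset
#'
#' @param samples list of [VolumeSample-class] objects.
#' @param paths character vector of image paths (prefixes), same length.
#' @param file output CSV path.
#' @return invisibly, the manifest data.frame (sample_id, path, label).
#' @export
writeManifest <- function(samples, paths, file) {
  df <- data.frame(sample_id = sprintf("S%04d", seq_along(samples)),
                   path = paths,
                   label = sampleLabels(samples))
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
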