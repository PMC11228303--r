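#' QuantizedImage: gray-level discretized image with a region of interest
#'
#' Holds an integer gray-level image or volume whose region-of-interest (ROI)
#' voxels carry levels in `1..Ng` (equal-width binning of the original
#' intensities) and whose non-ROI voxels are 0.  All texture matrices (GLCM,
#' GLRLM, GLSZM) are built from this substrate.
#'
#' @slot levels integer array; `1..Ng` inside the ROI, 0 outside.
#' @slot Ng number of gray levels.
#' @slot roi logical array, same dimensions as `levels`.
#' @slot original the real-valued source image.
#' @seealso [quantizeImage()]
#' @export
setClass("QuantizedImage",
  representation(levels = "array", Ng = "integer", roi = "array",
                 original = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@levels), dim(object@roi)))
      msg <- c(msg, "levels and roi must have identical dimensions")
    lv <- object@levels[object@roi]
    if (length(lv) == 0L) msg <- c(msg, "ROI must be non-empty")
    if (length(lv) && (any(lv < 1L) || any(lv > object@Ng)))
      msg <- c(msg, "ROI levels must lie in [1, Ng]")
    if (any(object@levels[!object@roi] != 0L))
      msg <- c(msg, "non-ROI voxels must be level 0")
    if (length(msg)) msg else TRUE
  })

#' TextureMatrix: GLCM / GLRLM / GLSZM count matrix
#'
#' A non-negative count (or normalized probability) matrix together with its
#' provenance: the matrix family, the displacement distance and direction
#' offset (GLCM/GLRLM; the GLSZM is direction-free).
#'
#' @slot kind one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`.
#' @slot counts numeric matrix; GLCM is Ng x Ng, GLRLM is Ng x Lmax,
#'   GLSZM is Ng x Smax.
#' @slot distance integer displacement (GLCM only; 0 otherwise).
#' @slot offset integer voxel offset defining the direction (empty for GLSZM).
#' @slot normalized logical; `TRUE` once the matrix sums to one.
#' @export
setClass("TextureMatrix",
  representation(kind = "character", counts = "matrix", distance = "integer",
                 offset = "integer", normalized = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("GLCM", "GLRLM", "GLSZM"))
      msg <- c(msg, "kind must be GLCM, GLRLM or GLSZM")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (isTRUE(object@normalized) &&
        abs(sum(object@counts) - 1) > 1e-12)
      msg <- c(msg, "normalized matrix must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' RadiomicsVector: named hand-crafted feature values for one sample
#'
#' @slot values named numeric vector in a fixed, reproducible order.
#' @slot flagged names of features that were degenerate (for example skewness
#'   of a constant region) and imputed 0 so the vector length stays fixed.
#' @export
setClass("RadiomicsVector",
  representation(values = "numeric", flagged = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@values)) || anyNA(names(object@values)))
      msg <- c(msg, "values must be named")
    if (anyNA(object@values)) msg <- c(msg, "values must not contain NA/NaN")
    if (length(msg)) msg else TRUE
  })

#' VolumeSample: channel-first image/volume with mask, foreground and label
#'
#' The network's input unit: a real-valued array in `(C, H, W)` or
#' `(C, H, W, D)` layout, a binary lesion mask, the binary foreground
#' (non-zero region) and a class label (0 = benign, 1 = malignant).
#'
#' @slot image numeric array, channel-first.
#' @slot mask logical array over the spatial dimensions.
#' @slot foreground logical array over the spatial dimensions.
#' @slot label integer, 0 or 1.
#' @export
setClass("VolumeSample",
  representation(image = "array", mask = "array", foreground = "array",
                 label = "integer"),
  validity = function(object) {
    msg <- character()
    sdim <- dim(object@image)[-1]
    if (!identical(dim(object@mask), sdim))
      msg <- c(msg, "mask dimensions must match the spatial image dimensions")
    if (!identical(dim(object@foreground), sdim))
      msg <- c(msg, "foreground dimensions must match the spatial image dimensions")
    if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
    if (length(msg)) msg else TRUE
  })

#' FusionNet: the multi-scale residual network
#'
#' Wraps the layer graph (Seq-ResNet blocks, transpose-convolution
#' up/down-sampling modules, pooling and fully connected head) together with
#' its configuration and training history.
#'
#' @slot layers the layer graph (internal representation).
#' @slot config the [fusionNetConfig()] the model was built from.
#' @slot trained logical.
#' @slot history per-epoch training loss/accuracy, once trained.
#' @export
setClass("FusionNet",
  representation(layers = "list", config = "list", trained = "logical",
                 history = "list"))

#' SVMModel: a fitted (multi-)kernel support vector machine
#'
#' @slot fit the underlying fitted solver object.
#' @slot kernel selected kernel, one of `"linear"`, `"polynomial"`, `"rbf"`.
#' @slot hyperparams list with `C`, `gamma`, `degree`, `coef0`.
#' @slot report data.frame of inner-CV accuracy per candidate configuration.
#' @export
setClass("SVMModel",
  representation(fit = "ANY", kernel = "character", hyperparams = "list",
                 report = "data.frame"))

# ------------------------------------------------------------- accessors -----

#' @describeIn QuantizedImage number of gray levels
#' @param object a `QuantizedImage`
#' @export
setGeneric("nGrayLevels", function(object) standardGeneric("nGrayLevels"))
#' @export
setMethod("nGrayLevels", "QuantizedImage", function(object) object@Ng)

#' @describeIn QuantizedImage the ROI mask
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @export
setMethod("roiMask", "QuantizedImage", function(object) object@roi)

#' @describeIn QuantizedImage the integer level array
#' @export
setGeneric("grayLevels", function(object) standardGeneric("grayLevels"))
#' @export
setMethod("grayLevels", "QuantizedImage", function(object) object@levels)

#' @describeIn TextureMatrix the count matrix
#' @param object a `TextureMatrix`
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @export
setMethod("counts", "TextureMatrix", function(object) object@counts)

#' @describeIn TextureMatrix matrix family ("GLCM", "GLRLM" or "GLSZM")
#' @export
setGeneric("textureKind", function(object) standardGeneric("textureKind"))
#' @export
setMethod("textureKind", "TextureMatrix", function(object) object@kind)

#' @describeIn TextureMatrix whether the matrix has been normalized to sum 1
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @export
setMethod("isNormalized", "TextureMatrix", function(object) object@normalized)

#' @describeIn RadiomicsVector feature values as a named numeric vector
#' @param object a `RadiomicsVector`
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @export
setMethod("featureValues", "RadiomicsVector", function(object) object@values)

#' @describeIn RadiomicsVector names of degenerate, zero-imputed features
#' @export
setGeneric("flaggedFeatures", function(object) standardGeneric("flaggedFeatures"))
#' @export
setMethod("flaggedFeatures", "RadiomicsVector", function(object) object@flagged)

#' @describeIn VolumeSample channel-first image array
#' @param object a `VolumeSample`
#' @export
setGeneric("sampleImage", function(object) standardGeneric("sampleImage"))
#' @export
setMethod("sampleImage", "VolumeSample", function(object) object@image)

#' @describeIn VolumeSample lesion mask
#' @export
setGeneric("sampleMask", function(object) standardGeneric("sampleMask"))
#' @export
setMethod("sampleMask", "VolumeSample", function(object) object@mask)

#' @describeIn VolumeSample foreground (non-zero region) indicator
#' @export
setGeneric("sampleForeground", function(object) standardGeneric("sampleForeground"))
#' @export
setMethod("sampleForeground", "VolumeSample", function(object) object@foreground)

#' @describeIn VolumeSample class label (0 benign, 1 malignant)
#' @export
setGeneric("sampleLabel", function(object) standardGeneric("sampleLabel"))
#' @export
setMethod("sampleLabel", "VolumeSample", function(object) object@label)

#' @describeIn FusionNet number of Seq-ResNet blocks in the layer graph
#' @param object a `FusionNet`
#' @export
setGeneric("nSeqResBlocks", function(object) standardGeneric("nSeqResBlocks"))
#' @export
setMethod("nSeqResBlocks", "FusionNet", function(object) {
  .countBlocks <- function(layer) {
    n <- if (identical(layer$type, "seqres")) 1L else 0L
    for (s in layer$sub) n <- n + .countBlocks(s)
    n
  }
  sum(vapply(object@layers, .countBlocks, integer(1)))
})

#' @describeIn FusionNet total number of trainable parameters
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))
#' @export
setMethod("nParameters", "FusionNet", function(object) {
  sum(vapply(.modelParams(object@layers), length, integer(1)))
})

# ------------------------------------------------------------ show methods ---

setMethod("show", "QuantizedImage", function(object) {
  cat("QuantizedImage:", paste(dim(object@levels), collapse = " x "),
      "| Ng =", object@Ng, "| ROI voxels =", sum(object@roi), "\n")
})

setMethod("show", "TextureMatrix", function(object) {
  cat(object@kind, "TextureMatrix:", nrow(object@counts), "x",
      ncol(object@counts),
      if (object@normalized) "(normalized)" else "(counts)")
  if (length(object@offset))
    cat(" | offset (", paste(object@offset, collapse = ","), ")", sep = "")
  cat("\n")
})

setMethod("show", "RadiomicsVector", function(object) {
  cat("RadiomicsVector with", length(object@values), "features")
  if (length(object@flagged))
    cat(" (", length(object@flagged), " degenerate, imputed 0)", sep = "")
  cat("\n")
})

setMethod("show", "VolumeSample", function(object) {
  d <- dim(object@image)
  cat("VolumeSample: image (", paste(d, collapse = ", "), "), label ",
      object@label, ", mask voxels ", sum(object@mask), "\n", sep = "")
})

setMethod("show", "FusionNet", function(object) {
  cat("FusionNet:", nSeqResBlocks(object), "Seq-ResNet blocks,",
      nParameters(object), "parameters,",
      if (object@trained) "trained" else "untrained", "\n")
})

setMethod("show", "SVMModel", function(object) {
  cat("SVMModel: kernel =", object@kernel, "| C =", object@hyperparams$C, "\n")
})
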