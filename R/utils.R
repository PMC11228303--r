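# Shared internal helpers: seeded RNG derivation, separable Gaussian blur,
# resizing wrappers over the compiled kernels.

#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage mixes
#' the master seed with a short tag so stages are decoupled but reproducible.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the consumer stage.
#' @return an integer seed below 2^31.
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483587)
}

# run code under a local RNG state, restoring the caller's stream
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur along every spatial axis of a 2D or 3D array
gaussBlurArray <- function(a, sigma) {
  d <- dim(a)
  k <- gaussKernel1d(sigma)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[ax])
    m <- .cpp_conv1d_cols(m, k)
    ap <- array(m, dim(ap))
    a <- aperm(ap, order(perm))
  }
  a
}

# resize a 2D matrix; method in c("nearest", "bilinear", "cubic")
resizeMatrix <- function(x, target, method = "bilinear") {
  code <- match(match.arg(method, c("nearest", "bilinear", "cubic")),
                c("nearest", "bilinear", "cubic")) - 1L
  .cpp_resize2(x, as.integer(target[1]), as.integer(target[2]), code)
}

#' Stack samples into the network's batch layout
#'
#' Converts a list of 2D [VolumeSample-class] objects, each `(C, H, W)`, into
#' the `(H, W, C, N)` array the network consumes.
#'
#' @param samples list of [VolumeSample-class] objects with equal dimensions.
#' @return numeric array `(H, W, C, N)`.
#' @export
stackSamples <- function(samples) {
  stopifnot(length(samples) > 0)
  d <- dim(sampleImage(samples[[1]]))
  stopifnot(length(d) == 3)
  out <- array(0, c(d[2], d[3], d[1], length(samples)))
  for (i in seq_along(samples))
    out[, , , i] <- aperm(sampleImage(samples[[i]]), c(2, 3, 1))
  out
}

#' Labels of a list of samples
#'
#' @param samples list of [VolumeSample-class] objects.
#' @return integer vector of 0/1 labels.
#' @export
sampleLabels <- function(samples) {
  vapply(samples, sampleLabel, integer(1))
}
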