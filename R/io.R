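# Reading and writing standard formats: NIfTI volumes (single 4D file, or
# the per-channel _000.._003 quartet dialect), CSV feature tables, JSON
# configuration and reports.

#' Read a volume into channel-first layout
#'
#' Accepts either a single NIfTI file (3D, or 4D with channels on the last
#' axis) or a path prefix whose per-channel files `<prefix>_000.nii.gz`,
#' `<prefix>_001.nii.gz`, ... are stacked in suffix order.
#'
#' @param path NIfTI file path or per-channel prefix.
#' @return list with `image` (channel-first array `(C, H, W[, D])`) and
#'   `affine` (4x4 orientation matrix of the first file read).
#' @export
readVolume <- function(path) {
  if (file.exists(path)) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    a <- as.array(img)
    d <- dim(a)
    if (length(d) == 4L) {
      return(list(image = aperm(a, c(4, 1, 2, 3)), affine = aff))
    }
    arr <- array(a, c(1L, d))
    return(list(image = arr, affine = aff))
  }
  files <- Sys.glob(sprintf("%s_[0-9][0-9][0-9].nii*", path))
  if (length(files) == 0)
    stop("file not found: ", path, " (no such file or per-channel set)")
  files <- sort(files)
  chans <- lapply(files, RNifti::readNifti)
  aff <- RNifti::xform(chans[[1]])
  d <- dim(as.array(chans[[1]]))
  out <- array(0, c(length(chans), d))
  for (i in seq_along(chans)) {
    a <- as.array(chans[[i]])
    if (!identical(dim(a), d))
      stop("channel files disagree on dimensions: ", files[i])
    if (length(d) == 2L) out[i, , ] <- a else out[i, , , ] <- a
  }
  list(image = out, affine = aff)
}

#' Write a feature table to CSV
#'
#' @param table data.frame with `sample_id` first and `label` last.
#' @param file output path.
#' @export
writeFeatureTable <- function(table, file) {
  ord <- c("sample_id", setdiff(names(table), c("sample_id", "label")),
           "label")
  write.csv(table[ord], file, row.names = FALSE)
  invisible(file)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param file CSV path.
#' @return data.frame.
#' @export
readFeatureTable <- function(file) {
  read.csv(file, check.names = FALSE)
}

# md5 digest of an arbitrary R object (via its serialization) or a file
.digestObject <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

.digestFile <- function(path) unname(tools::md5sum(path))
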