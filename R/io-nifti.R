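#' Write a volume as NIfTI-1
#'
#' Writes a 3-D or 4-D array with the grid affine in both sform and
#' qform.  Integer arrays are stored as int32 (exact label round trip),
#' numeric arrays as float32.
#'
#' @param data 3-D or 4-D array (logical masks are stored as int32 0/1).
#' @param grid the `volume_grid` of the first three dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  stopifnot(identical(dim(data)[1:3], as.integer(grid$shape)))
  if (is.logical(data)) {
    data <- array(as.integer(data), dim(data))
  }
  dt <- if (is.integer(data)) "int32" else "float"
  im <- RNifti::asNifti(data)
  affine <- grid$affine
  storage.mode(affine) <- "double"
  RNifti::pixdim(im) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::qform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path file path.
#' @return list with `data` (array) and `grid` (a `volume_grid` derived
#'   from the NIfTI affine).
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(im), dimnames = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < 1e-12) stop("volume affine is not invertible")
  dm <- dim(im)
  grid <- volume_grid(dm[1:3], affine = affine)
  data <- array(as.vector(im), dm)
  list(data = data, grid = grid)
}
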