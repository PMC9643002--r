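#' Volume grid: shape, affine and voxel size
#'
#' The coordinate frame shared by all volumes in a pipeline run.  The affine
#' is a 4x4 matrix mapping 0-based voxel indices (voxel centres at integer
#' indices) to world coordinates in mm.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 voxel-index-to-world transform; defaults to a
#'   RAS-aligned scaling by `voxel_size` with the centre of voxel
#'   `(0,0,0)` at the world origin.
#' @param voxel_size mm per axis (length 1 or 3); ignored when `affine`
#'   is supplied (it is then derived from the affine columns).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine = NULL, voxel_size = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  if (is.null(affine)) {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    stopifnot(all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
    if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(shape = shape, affine = affine, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `volume_grid`.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume <- function(grid) abs(det(grid$affine[1:3, 1:3]))

# world (n x 3, mm) -> continuous 0-based voxel index (n x 3)
world_to_voxel <- function(grid, pts) {
  pts <- rbind_pts(pts)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

# continuous voxel index (n x 3) -> world mm
voxel_to_world <- function(grid, idx) {
  idx <- rbind_pts(idx)
  t(grid$affine[1:3, 1:3] %*% t(idx) + grid$affine[1:3, 4])
}

# containing 0-based voxel of world points: floor(index + 0.5)
containing_voxel <- function(grid, pts) {
  u <- world_to_voxel(grid, pts)
  storage.mode(u) <- "double"
  v <- floor(u + 0.5)
  storage.mode(v) <- "integer"
  v
}

# is a 0-based voxel index triple inside the grid?
voxel_in_grid <- function(grid, v) {
  v <- rbind_pts(v)
  v[, 1] >= 0L & v[, 1] < grid$shape[1] &
    v[, 2] >= 0L & v[, 2] < grid$shape[2] &
    v[, 3] >= 0L & v[, 3] < grid$shape[3]
}

# 0-based voxel triples -> 1-based linear index into an array of grid shape
voxel_linear <- function(grid, v) {
  v <- rbind_pts(v)
  1L + v[, 1] + grid$shape[1] * (v[, 2] + grid$shape[2] * v[, 3])
}

# 3x4 row-major transform blocks used by the C++ kernels
world2vox34 <- function(grid) solve(grid$affine)[1:3, , drop = FALSE]
vox2world34 <- function(grid) grid$affine[1:3, , drop = FALSE]

rbind_pts <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3L) else as.matrix(p)
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}
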