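#' Super-resolution fine grid
#'
#' Subdivides every parent voxel by an integer factor per axis; the fine
#' grid covers exactly the parent field of view.
#'
#' @param grid parent `volume_grid`.
#' @param factor integer >= 1, scalar or per-axis.
#' @return a `volume_grid` with classes `c("fine_grid", "volume_grid")`
#'   and fields `parent` and `factor`.
#' @export
fine_grid <- function(grid, factor = 5L) {
  factor <- rep_len(as.integer(factor), 3L)
  stopifnot(all(factor >= 1L))
  shape <- grid$shape * factor
  A <- grid$affine
  Af <- A
  Af[1:3, 1:3] <- A[1:3, 1:3] %*% diag(1 / factor)
  # fine voxel (0,0,0) centre: parent voxel (0,0,0) corner + half a fine voxel
  corner <- A[1:3, 1:3] %*% rep(-0.5, 3) + A[1:3, 4]
  Af[1:3, 4] <- corner + Af[1:3, 1:3] %*% rep(0.5, 3)
  out <- volume_grid(shape, affine = Af)
  out$parent <- grid
  out$factor <- factor
  class(out) <- c("fine_grid", "volume_grid")
  out
}

#' Track-density map on a (fine) grid
#'
#' Each voxel's value is the number of distinct streamlines whose
#' polyline intersects it (every streamline counted at most once per
#' voxel), or their weight sum when weights are supplied.
#'
#' @param tractogram a `tractogram`.
#' @param grid target `volume_grid` (typically a [fine_grid()]).
#' @param weights optional aligned streamline weights.
#' @return 3-D numeric array on `grid`.
#' @export
tdi_map <- function(tractogram, grid, weights = NULL) {
  w <- if (is.null(weights)) numeric(0) else as.numeric(weights)
  if (length(w) && length(w) != length(tractogram))
    stop("weights are not aligned to the tractogram")
  v <- cpp_tdi(tractogram$streamlines, world2vox34(grid),
               as.integer(grid$shape), w)
  array(v, grid$shape)
}

#' Endpoint density map
#'
#' Bins both endpoints of every streamline into their containing fine
#' voxel (increment 1, or the streamline weight).  With a restriction
#' mask (on the parent grid of a [fine_grid()], or on `grid` itself),
#' only endpoints inside it are binned.
#'
#' @param tractogram a `tractogram`.
#' @param grid target `volume_grid` (typically a [fine_grid()]).
#' @param weights optional aligned streamline weights.
#' @param restrict optional logical 3-D mask on the parent grid.
#' @return an object of class `endpoint_density_map`: `data` (3-D
#'   array), `grid`, `weighted` flag and `n_mapped` endpoint count.
#' @export
endpoint_density_map <- function(tractogram, grid, weights = NULL,
                                 restrict = NULL) {
  n <- length(tractogram)
  if (n == 0L)
    return(structure(list(data = array(0, grid$shape), grid = grid,
                          weighted = !is.null(weights), n_mapped = 0L),
                     class = "endpoint_density_map"))
  ep <- streamline_endpoints(tractogram)
  wstr <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(wstr) != n) stop("weights are not aligned to the tractogram")
  wep <- rep(wstr, each = 2L)
  keep <- rep(TRUE, nrow(ep))
  if (!is.null(restrict)) {
    pgrid <- if (inherits(grid, "fine_grid")) grid$parent else grid
    stopifnot(identical(dim(restrict), as.integer(pgrid$shape)))
    v <- containing_voxel(pgrid, ep)
    ok <- voxel_in_grid(pgrid, v)
    keep <- ok
    keep[ok] <- restrict[v[ok, , drop = FALSE] + 1L]
  }
  vol <- array(0, grid$shape)
  if (any(keep)) {
    vf <- containing_voxel(grid, ep[keep, , drop = FALSE])
    okf <- voxel_in_grid(grid, vf)
    lin <- voxel_linear(grid, vf[okf, , drop = FALSE])
    ww <- wep[keep][okf]
    acc <- tapply(ww, lin, sum)
    vol[as.integer(names(acc))] <- as.numeric(acc)
    n_mapped <- sum(okf)
  } else n_mapped <- 0L
  structure(list(data = vol, grid = grid, weighted = !is.null(weights),
                 n_mapped = as.integer(n_mapped)),
            class = "endpoint_density_map")
}

#' @export
print.endpoint_density_map <- function(x, ...) {
  cat("endpoint_density_map:", paste(x$grid$shape, collapse = "x"),
      "voxels,", x$n_mapped, "endpoints",
      if (x$weighted) "(weighted)" else "", "\n")
  invisible(x)
}

#' Voxel-wise average of endpoint density maps
#'
#' @param maps list of `endpoint_density_map` objects on identical grids
#'   with identical weighted flags.
#' @return an `endpoint_density_map` holding the arithmetic mean.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g <- maps[[1]]$grid
  wf <- maps[[1]]$weighted
  for (m in maps) {
    if (!grids_equal(g, m$grid)) stop("maps are on different grids")
    if (!identical(wf, m$weighted)) stop("maps mix weighted flags")
  }
  dat <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  structure(list(data = dat, grid = g, weighted = wf,
                 n_mapped = as.integer(round(mean(vapply(
                   maps, function(m) as.numeric(m$n_mapped), numeric(1)))))),
            class = "endpoint_density_map")
}

#' Window a density map for display
#'
#' Values below the lower threshold become background (zero); values
#' above the upper threshold are clamped to it; the rest are mapped
#' linearly onto the intensity scale.  The lower threshold is inclusive.
#'
#' @param map an `endpoint_density_map` or numeric array.
#' @param scale intensity scale `c(min, max)`, default `c(0, 0.05)`.
#' @param thresholds display thresholds `c(min, max)`, default
#'   `c(0.02, 0.5)`.
#' @return list with `display` (values in `[0, 1]`), `thresholded` (the
#'   clamped data) and `quantised` (8-bit integer variant).
#' @export
window_for_display <- function(map, scale = c(0, 0.05),
                               thresholds = c(0.02, 0.5)) {
  if (scale[1] >= scale[2]) stop("scale min must be < scale max")
  if (thresholds[1] >= thresholds[2])
    stop("threshold min must be < threshold max")
  x <- if (inherits(map, "endpoint_density_map")) map$data else map
  th <- ifelse(x < thresholds[1], 0, pmin(x, thresholds[2]))
  disp <- (pmin(pmax(th, scale[1]), scale[2]) - scale[1]) /
    (scale[2] - scale[1])
  disp[th == 0] <- 0
  q <- array(as.integer(round(disp * 255)), dim(as.array(x)))
  list(display = array(disp, dim(as.array(x))),
       thresholded = array(th, dim(as.array(x))), quantised = q)
}
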