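#' Five-tissue-type partial-volume image
#'
#' A 4-D volume with five partial-volume channels per voxel, in the MRtrix
#' 5TT channel order: (1) cortical grey matter, (2) subcortical grey
#' matter, (3) white matter, (4) CSF, (5) pathological / no-priors tissue.
#'
#' @param data 4-D numeric array `(nx, ny, nz, 5)`; every channel in
#'   `[0, 1]` with per-voxel channel sums `<= 1 + 1e-6`.
#' @param grid the `volume_grid` of the volume.
#' @return an object of class `tissue5tt`.
#' @export
tissue5tt <- function(data, grid) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == 5L,
            identical(dim(data)[1:3], as.integer(grid$shape)))
  if (min(data) < -1e-9 || max(data) > 1 + 1e-6)
    stop("tissue partial volumes must lie in [0, 1]")
  sums <- rowSums(matrix(data, ncol = 5L))
  if (max(sums) > 1 + 1e-6)
    stop("per-voxel tissue channel sums must be <= 1")
  structure(list(data = data, grid = grid), class = "tissue5tt")
}

#' @export
print.tissue5tt <- function(x, ...) {
  cat("tissue5tt:", paste(x$grid$shape, collapse = "x"), "voxels\n")
  invisible(x)
}

t5_channel <- function(t5, k) t5$data[, , , k]

#' Grey-matter/white-matter interface mask
#'
#' Flags voxels at the GM/WM interface: a voxel is flagged when its
#' combined (cortical + subcortical) GM partial volume is `>= 0.5` and at
#' least one 6-connected neighbour has WM `>= 0.5`, or vice versa.
#'
#' @param t5 a [tissue5tt()].
#' @return logical 3-D array.
#' @export
compute_gmwmi <- function(t5) {
  gm <- t5_channel(t5, 1) + t5_channel(t5, 2) >= 0.5
  wm <- t5_channel(t5, 3) >= 0.5
  nb_gm <- neighbour_any(gm)
  nb_wm <- neighbour_any(wm)
  (gm & nb_wm) | (wm & nb_gm)
}

# any 6-connected neighbour TRUE
neighbour_any <- function(mask) {
  out <- array(FALSE, dim(mask))
  for (k in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3)
    d[k] <- s
    out <- out | shift_mask(mask, d)
  }
  out
}

#' Amend a 5TT image to the modified 5TT (m5TT)
#'
#' Removes the portion of the grey/white interface immediately inferior to
#' the hippocampus and re-labels the hippocampus itself so that streamlines
#' can enter and move within it: (a) voxels of the extended mask (the
#' hippocampus mask translated 1..`depth` voxels along `inferior_axis`,
#' restricted to the GM/WM interface or grey-matter voxels of that band)
#' that are not hippocampus become pure white matter; (b) hippocampus
#' voxels become pure fifth tissue (no anatomical priors).  All other
#' voxels are unchanged.  The operation is idempotent.
#'
#' @param t5 a [tissue5tt()].
#' @param hippocampus_mask non-empty logical 3-D array.
#' @param inferior_axis signed coordinate axis (`"-z"` etc.).
#' @param depth how many voxels the inferior band extends (>= 1),
#'   default 2.
#' @return a new `tissue5tt` (the m5TT).
#' @export
amend_to_m5tt <- function(t5, hippocampus_mask, inferior_axis = "-z",
                          depth = 2L) {
  stopifnot(inherits(t5, "tissue5tt"), depth >= 1L)
  if (!any(hippocampus_mask)) stop("hippocampus mask is empty")
  dir <- parse_axis(inferior_axis)
  band <- array(FALSE, dim(hippocampus_mask))
  cur <- hippocampus_mask
  for (d in seq_len(depth)) {
    cur <- shift_mask(cur, dir)
    band <- band | cur
  }
  band <- band & !hippocampus_mask
  gmw <- compute_gmwmi(t5)
  gm_in_band <- band & (t5_channel(t5, 1) + t5_channel(t5, 2) >= 0.5)
  extra <- band & (gmw | gm_in_band)
  out <- t5$data
  for (k in 1:5) {
    ch <- out[, , , k]
    ch[extra] <- as.numeric(k == 3L)
    ch[hippocampus_mask] <- as.numeric(k == 5L)
    out[, , , k] <- ch
  }
  res <- tissue5tt(out, t5$grid)
  attr(res, "extended_mask") <- extra | hippocampus_mask
  res
}

act_state_names <- c("WM", "CORTICAL_GM", "SUBCORTICAL_GM", "CSF",
                     "NO_PRIORS", "OUTSIDE")

#' Tissue state at world points
#'
#' Trilinearly interpolates all five tissue channels at each point and
#' classifies the anatomically-constrained-tracking state: `OUTSIDE` when
#' the interpolated channel sum is `<= 0.5`, otherwise the argmax channel
#' with the deterministic tie-break precedence WM > cortical GM >
#' subcortical GM > no-priors > CSF.
#'
#' @param t5 a [tissue5tt()].
#' @param points world-mm point or n x 3 matrix.
#' @return list with `state` (character vector) and `fractions`
#'   (n x 5 matrix of interpolated partial volumes).
#' @export
act_state_at <- function(t5, points) {
  pts <- rbind_pts(points)
  if (any(!is.finite(pts))) stop("points must be finite")
  u <- world_to_voxel(t5$grid, pts)
  fr <- cpp_trilinear(as.numeric(t5$data), as.integer(dim(t5$data)), u)
  colnames(fr) <- c("cgm", "sgm", "wm", "csf", "path")
  prec_chan <- c(3L, 1L, 2L, 5L, 4L) # WM, cGM, sGM, no-priors, CSF
  prec_state <- c("WM", "CORTICAL_GM", "SUBCORTICAL_GM", "NO_PRIORS", "CSF")
  state <- vapply(seq_len(nrow(fr)), function(i) {
    v <- fr[i, ]
    if (sum(v) <= 0.5) return("OUTSIDE")
    prec_state[which.max(v[prec_chan])]
  }, character(1))
  list(state = state, fractions = fr)
}
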