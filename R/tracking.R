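#' Fibre-orientation distribution field
#'
#' Per-voxel even-order spherical-harmonic coefficients of the fibre
#' orientation distribution.
#'
#' @param coeff 4-D array `(nx, ny, nz, n_coef)` with
#'   `n_coef == sh_ncoef(lmax)`.
#' @param grid the `volume_grid`.
#' @param lmax even maximum harmonic order.
#' @return an object of class `fod_field`.
#' @export
fod_field <- function(coeff, grid, lmax) {
  check_lmax(lmax)
  stopifnot(length(dim(coeff)) == 4L,
            identical(dim(coeff)[1:3], as.integer(grid$shape)),
            dim(coeff)[4] == sh_ncoef(lmax))
  structure(list(coeff = coeff, grid = grid, lmax = as.integer(lmax)),
            class = "fod_field")
}

#' @export
print.fod_field <- function(x, ...) {
  cat("fod_field:", paste(x$grid$shape, collapse = "x"),
      "voxels, lmax", x$lmax, "\n")
  invisible(x)
}

#' Tractography parameters
#'
#' @param fod_cutoff minimum FOD amplitude for propagation, default 0.06.
#' @param min_length,max_length accepted streamline length bounds in mm
#'   (defaults 5 and 300).
#' @param step step size in mm; `NULL` means half the smallest voxel size
#'   of the grid in use.
#' @param max_angle maximum angle between consecutive steps, degrees.
#' @param max_attempts_per_seed multiplier for the global attempt budget
#'   (`n * max_attempts_per_seed`), default 1000.
#' @param max_trials rejection-sampling trials per direction draw.
#' @param backtrack enable truncate-and-resample on rejection events.
#' @param trunc_depth steps removed per backtrack.
#' @param retries backtrack retries per arm.
#' @param seed RNG seed used by the tracker (via `set.seed`); `NULL`
#'   leaves the RNG state untouched.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(fod_cutoff = 0.06, min_length = 5,
                            max_length = 300, step = NULL, max_angle = 45,
                            max_attempts_per_seed = 1000, max_trials = 50,
                            backtrack = TRUE, trunc_depth = 3, retries = 2,
                            seed = NULL) {
  stopifnot(fod_cutoff >= 0, min_length > 0, min_length < max_length,
            is.null(step) || step > 0, max_angle > 0, max_trials >= 1)
  structure(list(fod_cutoff = fod_cutoff, min_length = min_length,
                 max_length = max_length, step = step, max_angle = max_angle,
                 max_attempts_per_seed = max_attempts_per_seed,
                 max_trials = as.integer(max_trials),
                 backtrack = isTRUE(backtrack),
                 trunc_depth = as.integer(trunc_depth),
                 retries = as.integer(retries), seed = seed),
            class = "tracking_params")
}

resolve_step <- function(params, grid) {
  if (!is.null(params$step)) params$step else 0.5 * min(grid$voxel_size)
}

cpp_param_list <- function(params, grid) {
  list(step = resolve_step(params, grid), max_angle = params$max_angle,
       fod_cutoff = params$fod_cutoff, min_length = params$min_length,
       max_length = params$max_length, max_trials = params$max_trials,
       trunc_depth = params$trunc_depth, retries = params$retries,
       backtrack = params$backtrack)
}

streamline_status_names <- c("accepted", "rejected_short", "rejected_long",
                             "rejected_csf", "rejected_no_propagation")

#' Sample a propagation direction from an FOD
#'
#' Rejection sampling of a direction within `max_angle` of the previous
#' direction, with acceptance probability proportional to the FOD
#' amplitude; returns `NULL` when no direction within the cone exceeds the
#' cutoff after `max_trials` draws.
#'
#' @param coefficients SH coefficient vector.
#' @param previous unit direction of the previous step.
#' @param params a [tracking_params()].
#' @return a unit 3-vector, or `NULL`.
#' @export
sample_direction <- function(coefficients, previous,
                             params = tracking_params()) {
  stopifnot(abs(sqrt(sum(previous^2)) - 1) < 1e-6)
  lmax <- lmax_for_ncoef(length(coefficients))
  d <- cpp_sample_direction(as.numeric(coefficients), lmax,
                            as.numeric(previous), params$max_angle,
                            params$fod_cutoff, params$max_trials)
  if (length(d) == 0L) NULL else d
}

#' Track a single streamline from a seed point
#'
#' Bidirectional anatomically-constrained propagation from the seed; see
#' [generate_tractogram()] for the ACT rules.
#'
#' @param seed world-mm seed point (must be inside the field of view).
#' @param fod a [fod_field()].
#' @param t5 a [tissue5tt()].
#' @param params a [tracking_params()].
#' @param direction optional initial unit direction (random from the FOD
#'   when `NULL`).
#' @return list with `points` (n x 3 matrix, world mm) and `status` (one
#'   of `accepted`, `rejected_short`, `rejected_long`, `rejected_csf`,
#'   `rejected_no_propagation`).
#' @export
track_from_seed <- function(seed, fod, t5, params = tracking_params(),
                            direction = NULL) {
  seed <- as.numeric(seed)
  u <- drop(world_to_voxel(fod$grid, seed))
  if (any(u < -0.5) || any(u > fod$grid$shape - 0.5))
    stop("seed outside the field of view")
  if (!is.null(params$seed)) set.seed(params$seed)
  dirs <- if (is.null(direction)) NULL else matrix(direction, ncol = 3)
  res <- cpp_track_seeds(as.numeric(fod$coeff), as.integer(dim(fod$coeff)),
                         as.numeric(t5$data), as.integer(dim(t5$data)),
                         world2vox34(fod$grid), vox2world34(fod$grid),
                         fod$lmax, cpp_param_list(params, fod$grid),
                         matrix(seed, ncol = 3), dirs)
  list(points = res$streamlines[[1]],
       status = streamline_status_names[res$status[1] + 1L])
}

#' Track one streamline per seed
#'
#' Like [track_from_seed()] but vectorised over a fixed set of seeds:
#' every seed is attempted exactly once and all results (including
#' rejected streamlines) are returned.  Useful for fixed-budget
#' experiments such as permeation comparisons.
#'
#' @param seeds n x 3 matrix of world-mm seed points.
#' @param fod a [fod_field()].
#' @param t5 a [tissue5tt()].
#' @param params a [tracking_params()]; its `seed` is honoured.
#' @return list with `streamlines` (list of point matrices; rejected
#'   attempts give 0-row matrices) and `status` (character vector).
#' @export
track_seeds <- function(seeds, fod, t5, params = tracking_params()) {
  seeds <- rbind_pts(seeds)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_track_seeds(as.numeric(fod$coeff), as.integer(dim(fod$coeff)),
                         as.numeric(t5$data), as.integer(dim(t5$data)),
                         world2vox34(fod$grid), vox2world34(fod$grid),
                         fod$lmax, cpp_param_list(params, fod$grid),
                         seeds, NULL)
  list(streamlines = res$streamlines,
       status = streamline_status_names[res$status + 1L])
}

#' Uniform seed points within a voxel mask
#'
#' @param n number of seeds.
#' @param mask logical 3-D array.
#' @param grid the `volume_grid` of the mask.
#' @return n x 3 matrix of world-mm points, one uniform position inside a
#'   uniformly chosen mask voxel each.
#' @export
mask_seed_points <- function(n, mask, grid) {
  vox <- which(mask, arr.ind = TRUE) - 1L
  if (!nrow(vox)) stop("seed mask is empty")
  pick <- sample.int(nrow(vox), n, replace = TRUE)
  u <- vox[pick, , drop = FALSE] +
    matrix(runif(3 * n) - 0.5, ncol = 3)
  voxel_to_world(grid, u)
}

#' Generate a tractogram
#'
#' Repeatedly draws seeds and tracks anatomically constrained streamlines
#' until `n` are accepted or the global attempt budget
#' (`n * max_attempts_per_seed`) is exhausted.  ACT rules: stepping into
#' CSF rejects (with optional backtracking), entering cortical or
#' subcortical GM terminates and accepts, the fifth (no-priors) tissue
#' applies no constraint (propagation continues while the FOD supports
#' it and ends there acceptably), leaving the field of view terminates
#' with acceptance contingent on the other endpoint; accepted streamlines
#' satisfy the length bounds.
#'
#' @param n number of accepted streamlines requested (>= 0).
#' @param fod a [fod_field()].
#' @param t5 a [tissue5tt()].
#' @param params a [tracking_params()].
#' @param seeding `"wm_proportional"` (seed voxels drawn with probability
#'   proportional to WM partial volume, uniform position within the
#'   voxel) or `"mask"` (uniform over `mask` voxels).
#' @param mask logical 3-D array, required for mask seeding.
#' @return an object of class `tractogram`.  If the budget is exhausted a
#'   partial tractogram is returned with a warning.
#' @export
generate_tractogram <- function(n, fod, t5, params = tracking_params(),
                                seeding = c("wm_proportional", "mask"),
                                mask = NULL) {
  seeding <- match.arg(seeding)
  stopifnot(n >= 0, inherits(fod, "fod_field"), inherits(t5, "tissue5tt"))
  grid <- fod$grid
  if (n == 0L)
    return(new_tractogram(list(), grid, params, n_requested = 0L,
                          seeding = seeding,
                          status_counts = setNames(integer(5),
                                                   streamline_status_names),
                          attempts = 0, budget_exhausted = FALSE))
  if (seeding == "wm_proportional") {
    wmv <- t5_channel(t5, 3)
    vox <- which(wmv > 0, arr.ind = TRUE) - 1L
    if (!nrow(vox)) stop("no white-matter voxels to seed from")
    pr <- wmv[wmv > 0]
  } else {
    if (is.null(mask)) stop("mask seeding requires a mask")
    vox <- which(mask, arr.ind = TRUE) - 1L
    if (!nrow(vox)) stop("seed mask is empty")
    pr <- rep(1, nrow(vox))
  }
  cdf <- cumsum(pr) / sum(pr)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_generate_tractogram(
    as.numeric(fod$coeff), as.integer(dim(fod$coeff)),
    as.numeric(t5$data), as.integer(dim(t5$data)),
    world2vox34(grid), vox2world34(grid), fod$lmax,
    cpp_param_list(params, grid), as.integer(n),
    matrix(as.numeric(vox), ncol = 3), cdf,
    as.numeric(n) * params$max_attempts_per_seed)
  counts <- setNames(as.integer(res$counts), streamline_status_names)
  if (res$budget_exhausted)
    warning("attempt budget exhausted: returning a partial tractogram")
  new_tractogram(res$streamlines, grid, params, n_requested = as.integer(n),
                 seeding = seeding, status_counts = counts,
                 attempts = res$attempts,
                 budget_exhausted = res$budget_exhausted)
}

new_tractogram <- function(streamlines, grid, params, n_requested, seeding,
                           status_counts, attempts, budget_exhausted) {
  structure(list(streamlines = streamlines, grid = grid, params = params,
                 n_requested = n_requested, seeding = seeding,
                 status_counts = status_counts, attempts = attempts,
                 budget_exhausted = budget_exhausted),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  cat("tractogram:", length(x$streamlines), "streamlines",
      sprintf("(%s seeding, %g attempts)\n",
              if (is.null(x$seeding)) "?" else x$seeding,
              if (is.null(x$attempts)) NA else x$attempts))
  invisible(x)
}

#' Concatenate tractograms sharing a grid
#' @param ... `tractogram` objects on the same grid.
#' @return a combined `tractogram`.
#' @export
combine_tractograms <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  g <- xs[[1]]$grid
  for (x in xs) {
    stopifnot(inherits(x, "tractogram"))
    if (!grids_equal(g, x$grid)) stop("tractograms are on different grids")
  }
  counts <- Reduce(`+`, lapply(xs, function(x) {
    sc <- x$status_counts
    if (is.null(sc)) setNames(integer(5), streamline_status_names) else sc
  }))
  new_tractogram(do.call(c, lapply(xs, `[[`, "streamlines")), g,
                 xs[[1]]$params,
                 n_requested = sum(vapply(xs, function(x)
                   as.integer(x$n_requested), integer(1))),
                 seeding = paste(vapply(xs, function(x)
                   as.character(x$seeding), character(1)), collapse = "+"),
                 status_counts = counts,
                 attempts = sum(vapply(xs, function(x)
                   as.numeric(x$attempts), numeric(1))),
                 budget_exhausted = any(vapply(xs, function(x)
                   isTRUE(x$budget_exhausted), logical(1))))
}

#' Streamline endpoints
#' @param tractogram a `tractogram`.
#' @return 2n x 3 matrix: first and last point of each streamline
#'   (interleaved by streamline).
#' @export
streamline_endpoints <- function(tractogram) {
  do.call(rbind, lapply(tractogram$streamlines, function(m)
    m[c(1L, nrow(m)), , drop = FALSE]))
}

streamline_lengths <- function(tractogram) {
  vapply(tractogram$streamlines, function(m) {
    d <- diff(m)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}
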