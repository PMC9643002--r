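#' Bundle specification for the synthetic phantom
#'
#' Describes one fibre bundle connecting a cortical source parcel to a
#' hippocampal target segment.  If `control_points` is `NULL` the bundle
#' path is placed automatically: a vertical run from the parcel block up
#' through the obstructing interface, then a smooth bend inside the
#' hippocampus that aligns with the long axis and stays within the target
#' segment.
#'
#' @param label integer parcel label (> 0).
#' @param name parcel name; a leading `"L_"`/`"R_"` prefix marks the
#'   hemisphere.
#' @param segment hippocampal target segment: `"head"`, `"body"` or
#'   `"tail"`.
#' @param medial logical; target the medial (`TRUE`) or lateral side of
#'   the hippocampus.
#' @param radius tube radius in mm.
#' @param density fibre density carried by the bundle (>= 0).
#' @param control_points optional k x 3 matrix of world-mm points
#'   overriding automatic placement.
#' @param is_mtl logical, flag the source parcel as medial temporal lobe.
#' @return a `bundle_spec` list.
#' @export
bundle_spec <- function(label, name, segment = c("head", "body", "tail"),
                        medial = TRUE, radius = 2, density = 1,
                        control_points = NULL, is_mtl = FALSE) {
  segment <- match.arg(segment)
  stopifnot(label > 0, density >= 0, radius > 0)
  if (!is.null(control_points)) control_points <- rbind_pts(control_points)
  structure(list(label = as.integer(label), name = as.character(name),
                 segment = segment, medial = isTRUE(medial), radius = radius,
                 density = density, control_points = control_points,
                 is_mtl = isTRUE(is_mtl)),
            class = "bundle_spec")
}

default_bundles <- function() {
  list(
    bundle_spec(101L, "L_HEADM", "head", medial = TRUE,  density = 2.0),
    bundle_spec(102L, "L_BODYL", "body", medial = FALSE, density = 1.5),
    bundle_spec(103L, "L_TAILM", "tail", medial = TRUE,  density = 1.0)
  )
}

#' Phantom configuration
#'
#' Encodes the geometry and ground truth of the synthetic phantom: a
#' brain-like volume (WM interior, CSF shell), a curved hippocampus with a
#' defined long axis, an optional one-voxel obstructing GM sheet
#' immediately inferior to it, and fibre bundles with known densities
#' connecting labelled cortical parcels to hippocampal segments.
#'
#' @param shape grid size in voxels, default `c(40, 40, 32)`.
#' @param voxel_size mm per axis, default 1 (isotropic).
#' @param bundles list of [bundle_spec()] objects (may be empty).
#' @param kappa Watson-like lobe sharpness for FOD synthesis (> 0).
#' @param lmax even spherical-harmonic order (>= 2), default 8.
#' @param seed integer recorded into provenance (the generator itself is
#'   fully deterministic).
#' @param inferior_axis signed coordinate axis pointing in the anatomical
#'   inferior direction, one of `"+x" "-x" "+y" "-y" "+z" "-z"`.
#' @param obstructing_interface logical; paint the grey-matter sheet that
#'   blocks the inferior hippocampal border in the unamended 5TT.
#' @param hippo_control_points k x 3 matrix of world-mm centreline control
#'   points, anterior first.
#' @param hippo_radius hippocampus tube radius in mm.
#' @param subcortical_block logical; include a small subcortical-GM block.
#' @param n_fit_points sphere sampling size for per-voxel FOD fits.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(40L, 40L, 32L), voxel_size = 1,
                           bundles = default_bundles(), kappa = 20, lmax = 8,
                           seed = 1L, inferior_axis = "-z",
                           obstructing_interface = TRUE,
                           hippo_control_points = NULL, hippo_radius = 2.5,
                           subcortical_block = TRUE, n_fit_points = 500) {
  check_lmax(lmax)
  if (lmax < 2) stop("lmax must be >= 2")
  stopifnot(kappa > 0, hippo_radius > 0)
  parse_axis(inferior_axis)
  for (b in bundles) {
    if (!inherits(b, "bundle_spec")) stop("bundles must be bundle_spec objects")
    if (b$density < 0) stop("bundle densities must be >= 0")
  }
  if (is.null(hippo_control_points))
    hippo_control_points <- rbind(c(20, 8, 18), c(17, 14, 18), c(16, 20, 18),
                                  c(17, 26, 18), c(20, 32, 18))
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 bundles = bundles, kappa = kappa, lmax = as.integer(lmax),
                 seed = as.integer(seed), inferior_axis = inferior_axis,
                 obstructing_interface = isTRUE(obstructing_interface),
                 hippo_control_points = rbind_pts(hippo_control_points),
                 hippo_radius = hippo_radius,
                 subcortical_block = isTRUE(subcortical_block),
                 n_fit_points = n_fit_points),
            class = "phantom_config")
}

# "+x"/"-y"/... -> signed unit integer 3-vector
parse_axis <- function(axis) {
  if (!is.character(axis) || length(axis) != 1L ||
      !axis %in% c("+x", "-x", "+y", "-y", "+z", "-z"))
    stop("inferior_axis must be one of \"+x\" \"-x\" \"+y\" \"-y\" \"+z\" \"-z\"")
  sgn <- if (substr(axis, 1, 1) == "+") 1L else -1L
  ax <- match(substr(axis, 2, 2), c("x", "y", "z"))
  v <- integer(3)
  v[ax] <- sgn
  v
}

# dense centreline samples (n x 3 world mm) through control points,
# natural cubic splines per coordinate over chord-length parameter
sample_centreline <- function(control_points, n = 256L) {
  cp <- rbind_pts(control_points)
  if (nrow(cp) < 2L) stop("centreline needs at least 2 control points")
  d <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  t0 <- c(0, cumsum(d)) / sum(d)
  tt <- seq(0, 1, length.out = n)
  out <- sapply(1:3, function(k)
    stats::spline(t0, cp[, k], xout = tt, method = "natural")$y)
  out
}

arc_fractions <- function(samples) {
  d <- sqrt(rowSums((samples[-1, , drop = FALSE] -
                     samples[-nrow(samples), , drop = FALSE])^2))
  a <- c(0, cumsum(d))
  a / a[length(a)]
}

# logical mask of voxels whose centre lies within `radius` of the polyline
tube_mask <- function(grid, samples, radius) {
  mask <- array(FALSE, grid$shape)
  lo <- pmax(floor(apply(samples, 2, min) - radius) - 1, 0)
  hi <- pmin(ceiling(apply(samples, 2, max) + radius) + 1, grid$shape - 1)
  idx <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  ctr <- voxel_to_world(grid, idx)
  keep <- nearest_sample(ctr, samples)$dist <= radius
  mask[idx[keep, , drop = FALSE] + 1L] <- TRUE
  mask
}

# nearest centreline sample for each point: list(index, dist)
nearest_sample <- function(pts, samples) {
  pts <- rbind_pts(pts)
  n <- nrow(pts)
  idx <- integer(n)
  dst <- numeric(n)
  chunk <- 2048L
  s2 <- rowSums(samples^2)
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    p <- pts[st:en, , drop = FALSE]
    d2 <- outer(rowSums(p^2), s2, "+") - 2 * p %*% t(samples)
    j <- max.col(-d2, ties.method = "first")
    idx[st:en] <- j
    dst[st:en] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(p)), j)]))
  }
  list(index = idx, dist = dst)
}

#' Long-axis scalar field over a hippocampus mask
#'
#' Assigns each mask voxel the normalised arc length (0 = anterior tip,
#' 1 = posterior tip) of its nearest point on the centreline, making
#' anatomical "thirds" computable as field intervals.
#'
#' @param mask logical 3-D array (the hippocampus).
#' @param control_points centreline control points (world mm, anterior
#'   first).
#' @param grid the `volume_grid` of `mask`.
#' @param max_distance error if any mask voxel centre is farther than this
#'   from the centreline (malformed phantom), default 6 mm.
#' @return numeric 3-D array with values in `[0, 1]` on the mask, `NA`
#'   elsewhere.
#' @export
long_axis_field <- function(mask, control_points, grid, max_distance = 6) {
  samples <- sample_centreline(control_points)
  af <- arc_fractions(samples)
  vox <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(vox) == 0L) stop("hippocampus mask is empty")
  ctr <- voxel_to_world(grid, vox)
  ns <- nearest_sample(ctr, samples)
  if (any(ns$dist > max_distance))
    stop("mask voxel farther than max_distance from the centreline")
  field <- array(NA_real_, dim(mask))
  field[mask] <- af[ns$index]
  field
}

#' Build the synthetic phantom
#'
#' Generates the five-tissue-type volume, FOD field, parcellation,
#' hippocampus mask and ground truth implied by a [phantom_config()].
#' Tissue layout: the outermost voxel layer is outside the head (all
#' zeros), the next layer is CSF, the interior is WM; bundle tubes are WM;
#' source parcels are cortical-GM blocks; the hippocampus (and, when
#' enabled, the obstructing sheet immediately inferior to it) is cortical
#' GM in this unamended 5TT.  Per-voxel FODs are synthesized from the
#' bundle tangent directions and densities via [synthesize_fod()];
#' overlapping bundles yield multi-lobed FODs.
#'
#' @param config a [phantom_config()].
#' @return an object of class `hippo_phantom`: `t5` (a `tissue5tt`),
#'   `fod` (a `fod_field`), `parcellation`, `hippocampus_mask`,
#'   `sheet_mask`, `long_axis`, `truth` (bundle table + centreline), and
#'   `grid`.
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- volume_grid(config$shape, voxel_size = config$voxel_size)
  shp <- grid$shape
  inf_dir <- parse_axis(config$inferior_axis)

  # hippocampus tube and long axis
  hip_samples <- sample_centreline(config$hippo_control_points)
  hippo <- tube_mask(grid, hip_samples, config$hippo_radius)
  if (!any(hippo)) stop("hippocampus mask is empty")
  lax <- long_axis_field(hippo, config$hippo_control_points, grid)
  sheet <- array(FALSE, shp)
  if (config$obstructing_interface) {
    sheet <- shift_mask(hippo, inf_dir) & !hippo
  }

  # bundle paths, tubes and tangents
  bundles <- lapply(config$bundles, function(b)
    resolve_bundle(b, config, grid, hip_samples, hippo))

  # ---- tissue channels ------------------------------------------------
  t5dat <- array(0, c(shp, 5L))
  interior <- array(FALSE, shp)
  interior[3:(shp[1] - 2), 3:(shp[2] - 2), 3:(shp[3] - 2)] <- TRUE
  head_mask <- array(FALSE, shp) # inside the "head" (brain incl. CSF shell)
  head_mask[2:(shp[1] - 1), 2:(shp[2] - 1), 2:(shp[3] - 1)] <- TRUE
  csf <- head_mask & !interior
  wm <- interior
  t5dat[, , , 3][wm] <- 1
  t5dat[, , , 4][csf] <- 1
  if (config$subcortical_block && all(shp >= c(34L, 12L, 14L))) {
    sg <- array(FALSE, shp)
    sg[29:32, 5:8, 7:10] <- TRUE # 1-based index block, away from the bundles
    sg <- sg & interior & !hippo & !sheet
    t5dat[, , , 2][sg] <- 1
    t5dat[, , , 3][sg] <- 0
  }
  parc_labels <- array(0L, shp)
  for (b in bundles) {
    blk <- b$parcel_mask & interior
    t5dat[, , , 1][blk] <- 1
    t5dat[, , , 2][blk] <- 0
    t5dat[, , , 3][blk] <- 0
    parc_labels[blk] <- b$label
  }
  gm_paint <- sheet | hippo
  t5dat[, , , 1][gm_paint] <- 1
  t5dat[, , , 2][gm_paint] <- 0
  t5dat[, , , 3][gm_paint] <- 0
  t5dat[, , , 4][gm_paint] <- 0
  t5 <- tissue5tt(t5dat, grid)

  # ---- FOD synthesis --------------------------------------------------
  nc <- sh_ncoef(config$lmax)
  coeff <- array(0, c(shp, nc))
  pops <- collect_populations(bundles, grid)
  if (length(pops$voxel)) {
    flat <- matrix(coeff, ncol = nc)
    for (i in seq_along(pops$voxel)) {
      flat[pops$voxel[i], ] <- synthesize_fod(pops$populations[[i]],
                                              kappa = config$kappa,
                                              lmax = config$lmax,
                                              n_points = config$n_fit_points)
    }
    coeff <- array(flat, c(shp, nc))
  }
  fod <- fod_field(coeff, grid, config$lmax)

  # ---- parcellation table and truth ----------------------------------
  if (length(bundles)) {
    tab <- data.frame(
      id = vapply(bundles, `[[`, integer(1), "label"),
      name = vapply(bundles, `[[`, character(1), "name"),
      hemisphere = vapply(bundles, function(b) hemisphere_of(b$name),
                          character(1)),
      is_MTL = vapply(bundles, `[[`, logical(1), "is_mtl"),
      is_hippocampus = FALSE,
      stringsAsFactors = FALSE)
    tab <- tab[!duplicated(tab$id), , drop = FALSE]
  } else {
    tab <- data.frame(id = integer(), name = character(),
                      hemisphere = character(), is_MTL = logical(),
                      is_hippocampus = logical(), stringsAsFactors = FALSE)
  }
  parcellation <- new_parcellation(parc_labels, tab, grid)
  truth_tab <- if (length(bundles)) data.frame(
    id = seq_along(bundles),
    parcel = vapply(bundles, `[[`, integer(1), "label"),
    name = vapply(bundles, `[[`, character(1), "name"),
    segment = vapply(bundles, `[[`, character(1), "segment"),
    medial = vapply(bundles, `[[`, logical(1), "medial"),
    density = vapply(bundles, `[[`, numeric(1), "density"),
    stringsAsFactors = FALSE
  ) else data.frame(id = integer(), parcel = integer(), name = character(),
                    segment = character(), medial = logical(),
                    density = numeric(), stringsAsFactors = FALSE)

  structure(list(
    t5 = t5, fod = fod, parcellation = parcellation,
    hippocampus_mask = hippo, sheet_mask = sheet, long_axis = lax,
    truth = list(bundles = truth_tab,
                 bundle_paths = lapply(bundles, `[[`, "samples"),
                 bundle_tubes = lapply(bundles, `[[`, "tube"),
                 bundle_cores = lapply(bundles, `[[`, "core"),
                 centreline = hip_samples),
    grid = grid, config = config), class = "hippo_phantom")
}

#' @export
print.hippo_phantom <- function(x, ...) {
  cat("hippo_phantom:", paste(x$grid$shape, collapse = "x"), "voxels,",
      nrow(x$truth$bundles), "bundle(s),",
      sum(x$hippocampus_mask), "hippocampus voxels\n")
  invisible(x)
}

hemisphere_of <- function(name) {
  if (startsWith(name, "L_")) "L" else if (startsWith(name, "R_")) "R"
  else "none"
}

shift_mask <- function(mask, dir) {
  out <- array(FALSE, dim(mask))
  shp <- dim(mask)
  src <- lapply(1:3, function(k) {
    if (dir[k] == 0L) seq_len(shp[k])
    else if (dir[k] > 0L) seq_len(shp[k] - 1L)
    else 2:shp[k]
  })
  dst <- lapply(1:3, function(k) src[[k]] + dir[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# place a bundle path automatically (or use explicit control points),
# sample it, compute tube mask and per-sample tangents, parcel block mask
resolve_bundle <- function(b, config, grid, hip_samples, hippo) {
  af <- arc_fractions(hip_samples)
  if (is.null(b$control_points)) {
    # target the interior of the segment and run the intra-hippocampal
    # extension away from the nearer boundary, leaving a margin so that
    # endpoint overshoot stays within the declared segment
    t_target <- switch(b$segment, head = 1 / 6, body = 0.45, tail = 0.80)
    i <- which.min(abs(af - t_target))
    ctr <- hip_samples[i, ]
    xoff <- if (b$medial) -1.2 else 1.2
    tx <- ctr[1] + xoff
    ty <- ctr[2]
    # the intra-hippocampal extension follows the curved centreline for
    # ~2.5 mm (anteriorly for head targets, posteriorly otherwise)
    arclen <- sum(sqrt(rowSums(diff(hip_samples)^2)))
    run <- if (b$segment == "head") -2.5 else 2.5
    j <- which.min(abs(af - (t_target + run / arclen)))
    endc <- hip_samples[j, ]
    mid <- function(a) ctr * (1 - a) + endc * a
    m1 <- mid(0.25)
    m2 <- mid(0.60)
    cp <- rbind(c(tx, ty, 5),
                c(tx, ty, 11),
                c(tx, ty, ctr[3] - 3.8),
                c(m1[1] + xoff, m1[2], ctr[3] - 1.6),
                c(m2[1] + xoff, m2[2], ctr[3] - 0.4),
                c(endc[1] + xoff, endc[2], endc[3] + 0.3))
  } else {
    cp <- b$control_points
  }
  samples <- sample_centreline(cp, n = 192L)
  tube <- tube_mask(grid, samples, b$radius)
  core <- tube_mask(grid, samples, max(b$radius - 1, 0.5))
  tangents <- path_tangents(samples)
  # parcel block: 5x5x5 cortical-GM cube around the path's far (start) end
  p0 <- samples[1, ]
  pm <- array(FALSE, grid$shape)
  v0 <- drop(containing_voxel(grid, p0))
  xr <- pmax(v0[1] - 2, 0):pmin(v0[1] + 2, grid$shape[1] - 1)
  yr <- pmax(v0[2] - 2, 0):pmin(v0[2] + 2, grid$shape[2] - 1)
  zr <- pmax(v0[3] - 2, 0):pmin(v0[3] + 2, grid$shape[3] - 1)
  pm[xr + 1L, yr + 1L, zr + 1L] <- TRUE
  c(b, list(samples = samples, tube = tube, core = core,
            tangents = tangents, parcel_mask = pm))
}

path_tangents <- function(samples) {
  n <- nrow(samples)
  tg <- samples[c(2:n, n), ] - samples[c(1, 1:(n - 1)), ]
  tg / sqrt(rowSums(tg^2))
}

# radial density taper: full density in the tube core, cosine falloff
# over the outermost 1 mm (a partial-volume-like soft edge, so painted
# fibre density decays where streamline coverage does)
tube_taper <- function(dist, radius, edge = 1) {
  inner <- radius - edge
  ifelse(dist <= inner, 1,
         0.5 * (1 + cos(pi * pmin(pmax(dist - inner, 0), edge) / edge)))
}

# gather per-voxel fibre populations from all bundle tubes
collect_populations <- function(bundles, grid) {
  vox <- integer(0)
  pops <- list()
  if (!length(bundles)) return(list(voxel = vox, populations = pops))
  env <- new.env(parent = emptyenv())
  for (b in bundles) {
    idx <- which(b$tube, arr.ind = TRUE) - 1L
    if (!nrow(idx)) next
    ctr <- voxel_to_world(grid, idx)
    ns <- nearest_sample(ctr, b$samples)
    lin <- voxel_linear(grid, idx)
    for (i in seq_along(lin)) {
      key <- as.character(lin[i])
      dens <- b$density * tube_taper(ns$dist[i], b$radius)
      if (dens <= 0) next
      pop <- list(direction = b$tangents[ns$index[i], ], density = dens)
      cur <- if (!is.null(env[[key]])) env[[key]] else list()
      env[[key]] <- c(cur, list(pop))
    }
  }
  keys <- ls(env)
  list(voxel = as.integer(keys),
       populations = lapply(keys, function(k) env[[k]]))
}
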