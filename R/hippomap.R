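#' Parcellation volume
#'
#' @param labels integer 3-D array (0 = unassigned).
#' @param table data frame with columns `id`, `name`, `hemisphere`
#'   (`"L"`, `"R"` or `"none"`), `is_MTL`, `is_hippocampus`.
#' @param grid the `volume_grid`.
#' @return an object of class `parcellation`.
#' @export
new_parcellation <- function(labels, table, grid) {
  stopifnot(identical(dim(labels), as.integer(grid$shape)))
  used <- sort(unique(as.integer(labels[labels != 0L])))
  if (!all(used %in% table$id))
    stop("label volume contains ids missing from the label table")
  if (any(table$is_hippocampus & table$id %in%
            table$id[!table$is_hippocampus & duplicated(table$id)]))
    stop("hippocampus labels must be disjoint from cortical labels")
  structure(list(labels = labels, table = table, grid = grid),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", nrow(x$table), "labels,",
      sum(x$labels != 0L), "labelled voxels\n")
  invisible(x)
}

#' Extract streamlines (and weights) with an endpoint in a mask
#'
#' A streamline is kept iff its first or last point falls inside a mask
#' voxel (containment via the inverse affine); weights are subset in the
#' same order.
#'
#' @param tractogram a `tractogram`.
#' @param weights numeric weights aligned to the tractogram.
#' @param mask logical 3-D array on the tractogram grid.
#' @return list with `tractogram` and `weights` (subset, same order).
#' @export
extract_endpoint_subset <- function(tractogram, weights, mask) {
  if (length(weights) != length(tractogram))
    stop("weights are not aligned to the tractogram")
  keep <- endpoint_in_mask(tractogram, mask)
  sub <- tractogram
  sub$streamlines <- tractogram$streamlines[keep$any]
  sub$n_requested <- NULL
  sub$status_counts <- NULL
  list(tractogram = sub, weights = as.numeric(weights)[keep$any])
}

# per-streamline endpoint-in-mask flags: list(first, last, any, both)
endpoint_in_mask <- function(tractogram, mask) {
  ep <- streamline_endpoints(tractogram)
  v <- containing_voxel(tractogram$grid, ep)
  ok <- voxel_in_grid(tractogram$grid, v)
  inm <- logical(nrow(v))
  inm[ok] <- mask[v[ok, , drop = FALSE] + 1L]
  first <- inm[seq(1L, length(inm), by = 2L)]
  last <- inm[seq(2L, length(inm), by = 2L)]
  list(first = first, last = last, any = first | last, both = first & last)
}

#' Split a hippocampus mask into head, body and tail
#'
#' Partition by the long-axis field with half-open intervals:
#' head `[0, b1)`, body `[b1, b2)`, tail `[b2, 1]`.
#'
#' @param mask logical 3-D hippocampus mask.
#' @param field long-axis field (from [long_axis_field()]), defined on
#'   every mask voxel.
#' @param boundaries increasing pair in (0, 1), default `c(1/3, 2/3)`.
#' @return an object of class `hippocampus_regions`: logical masks
#'   `whole`, `head`, `body`, `tail` (disjoint, union = whole).
#' @export
split_thirds <- function(mask, field, boundaries = c(1 / 3, 2 / 3)) {
  if (length(boundaries) != 2L || boundaries[1] >= boundaries[2] ||
      boundaries[1] <= 0 || boundaries[2] >= 1)
    stop("boundaries must be increasing within (0, 1)")
  f <- field[mask]
  if (any(is.na(f))) stop("long-axis field undefined on some mask voxels")
  head <- mask & !is.na(field) & field < boundaries[1]
  body <- mask & !is.na(field) & field >= boundaries[1] &
    field < boundaries[2]
  tail <- mask & !is.na(field) & field >= boundaries[2]
  structure(list(whole = mask, head = head, body = body, tail = tail),
            class = "hippocampus_regions")
}

#' @export
print.hippocampus_regions <- function(x, ...) {
  cat("hippocampus_regions: whole", sum(x$whole), "= head", sum(x$head),
      "+ body", sum(x$body), "+ tail", sum(x$tail), "voxels\n")
  invisible(x)
}

#' Assign endpoints to parcels
#'
#' Label of the containing voxel when non-zero; otherwise the label of
#' the nearest non-zero voxel centre within `search_radius`; otherwise 0.
#'
#' @param points world-mm point or n x 3 matrix.
#' @param parcellation a `parcellation`.
#' @param search_radius mm, default 2.
#' @return integer label vector (0 = unassigned).
#' @export
assign_parcel <- function(points, parcellation, search_radius = 2) {
  pts <- rbind_pts(points)
  grid <- parcellation$grid
  v <- containing_voxel(grid, pts)
  ok <- voxel_in_grid(grid, v)
  lab <- integer(nrow(pts))
  lab[ok] <- parcellation$labels[v[ok, , drop = FALSE] + 1L]
  miss <- which(lab == 0L)
  if (length(miss)) {
    nz <- which(parcellation$labels != 0L, arr.ind = TRUE) - 1L
    if (nrow(nz)) {
      ctr <- voxel_to_world(grid, nz)
      nzlab <- parcellation$labels[nz + 1L]
      ns <- nearest_sample(pts[miss, , drop = FALSE], ctr)
      hit <- ns$dist <= search_radius
      lab[miss[hit]] <- nzlab[ns$index[hit]]
    }
  }
  lab
}

#' Build the SIFT2-weight-sum connectivity table
#'
#' For each streamline with exactly one hippocampal endpoint and a
#' non-zero cortical parcel at the other endpoint, its weight is added to
#' that parcel's `whole` column and to exactly one of `head`/`body`/
#' `tail` according to the hippocampal endpoint's region.  Streamlines
#' with both endpoints in the hippocampus accumulate in the
#' intra-hippocampal bucket; streamlines whose other endpoint is
#' unassigned are dropped and counted.
#'
#' @param tractogram hippocampus tractogram (every streamline must have
#'   at least one endpoint in `regions$whole`).
#' @param weights aligned streamline weights.
#' @param parcellation a `parcellation`.
#' @param regions a [split_thirds()] result.
#' @param search_radius passed to [assign_parcel()].
#' @return a `connectivity_table` data frame (`parcel`, `name`,
#'   `hemisphere`, `is_MTL`, `whole`, `head`, `body`, `tail`) with
#'   attributes `intra_hippocampal`, `dropped_weight`, `n_dropped` and
#'   `total_weight`.
#' @export
build_connectivity_table <- function(tractogram, weights, parcellation,
                                     regions, search_radius = 2) {
  if (length(weights) != length(tractogram))
    stop("weights are not aligned to the tractogram")
  if (sum(regions$head) + sum(regions$body) + sum(regions$tail) !=
        sum(regions$whole) ||
      any((regions$head & regions$body) | (regions$head & regions$tail) |
            (regions$body & regions$tail)))
    stop("regions do not partition the hippocampus mask")
  w <- as.numeric(weights)
  inm <- endpoint_in_mask(tractogram, regions$whole)
  if (any(!inm$any))
    stop("streamline without a hippocampal endpoint in the tractogram")
  ep <- streamline_endpoints(tractogram)
  first <- ep[seq(1L, nrow(ep), by = 2L), , drop = FALSE]
  last <- ep[seq(2L, nrow(ep), by = 2L), , drop = FALSE]
  n <- length(tractogram)
  intra <- sum(w[inm$both])
  single <- which(!inm$both)
  hip_pt <- matrix(0, length(single), 3)
  oth_pt <- matrix(0, length(single), 3)
  hf <- inm$first[single]
  hip_pt[hf, ] <- first[single[hf], ]
  hip_pt[!hf, ] <- last[single[!hf], ]
  oth_pt[hf, ] <- last[single[hf], ]
  oth_pt[!hf, ] <- first[single[!hf], ]
  lab <- if (length(single)) assign_parcel(oth_pt, parcellation,
                                           search_radius) else integer(0)
  region_of <- function(pts) {
    v <- containing_voxel(tractogram$grid, pts)
    out <- character(nrow(v))
    okidx <- which(voxel_in_grid(tractogram$grid, v))
    idx <- v[okidx, , drop = FALSE] + 1L
    r <- character(length(okidx))
    r[regions$head[idx]] <- "head"
    r[regions$body[idx]] <- "body"
    r[regions$tail[idx]] <- "tail"
    out[okidx] <- r
    out
  }
  reg <- if (length(single)) region_of(hip_pt) else character(0)
  tab <- parcellation$table[!parcellation$table$is_hippocampus, ,
                            drop = FALSE]
  res <- data.frame(parcel = tab$id, name = tab$name,
                    hemisphere = tab$hemisphere, is_MTL = tab$is_MTL,
                    whole = 0, head = 0, body = 0, tail = 0,
                    stringsAsFactors = FALSE)
  dropped_w <- 0
  n_dropped <- 0L
  if (length(single)) {
    assigned <- lab != 0L & reg != ""
    dropped_w <- sum(w[single[!assigned]])
    n_dropped <- sum(!assigned)
    for (k in which(assigned)) {
      r <- match(lab[k], res$parcel)
      res$whole[r] <- res$whole[r] + w[single[k]]
      res[[reg[k]]][r] <- res[[reg[k]]][r] + w[single[k]]
    }
  }
  structure(res, class = c("connectivity_table", "data.frame"),
            intra_hippocampal = intra, dropped_weight = dropped_w,
            n_dropped = n_dropped, total_weight = sum(w))
}

#' Combine left- and right-hemisphere parcel values
#'
#' Per base parcel name (hemisphere prefix stripped), the bilateral value
#' is the sum (default) or mean of the hemispheres; unilateral parcels
#' pass through.
#'
#' @param table a `connectivity_table`.
#' @param how `"sum"` (default) or `"mean"`.
#' @return a `connectivity_table` keyed by base parcel name.
#' @export
combine_bilateral <- function(table, how = c("sum", "mean")) {
  how <- match.arg(how)
  base <- sub("^[LR]_", "", table$name)
  key <- paste(table$hemisphere, base)
  if (anyDuplicated(key[table$hemisphere %in% c("L", "R")]))
    stop("duplicate base parcel names within a hemisphere")
  agg <- function(col) {
    s <- tapply(table[[col]], base, sum)
    if (how == "mean") {
      n <- tapply(rep(1, nrow(table)), base, sum)
      s <- s / n
    }
    s
  }
  nm <- sort(unique(base))
  out <- data.frame(parcel = NA_integer_, name = nm,
                    hemisphere = "both", is_MTL = as.logical(
                      tapply(table$is_MTL, base, any)[nm]),
                    whole = as.numeric(agg("whole")[nm]),
                    head = as.numeric(agg("head")[nm]),
                    body = as.numeric(agg("body")[nm]),
                    tail = as.numeric(agg("tail")[nm]),
                    stringsAsFactors = FALSE)
  uni <- table$hemisphere == "none"
  out$hemisphere[out$name %in% table$name[uni]] <- "none"
  structure(out, class = c("connectivity_table", "data.frame"),
            intra_hippocampal = attr(table, "intra_hippocampal"),
            dropped_weight = attr(table, "dropped_weight"),
            n_dropped = attr(table, "n_dropped"),
            total_weight = attr(table, "total_weight"))
}

#' Percentage-of-connections columns
#'
#' Adds the two percentage columns: the percent of all cortical
#' connections accounted for by each parcel, and the percent when
#' medial-temporal-lobe (MTL) parcels are excluded from the denominator
#' (reported as `NA` for MTL parcels themselves).  Values are reported to
#' two decimals.
#'
#' @param table a `connectivity_table` with the `whole` column populated.
#' @param digits rounding for the reported percentages, default 2.
#' @return the table with `percent_all` and `percent_excl_MTL` columns.
#' @export
percent_columns <- function(table, digits = 2) {
  total_all <- sum(table$whole)
  total_non_mtl <- sum(table$whole[!table$is_MTL])
  if (total_all <= 0 || total_non_mtl <= 0)
    stop("connectivity totals are zero")
  table$percent_all <- round(100 * table$whole / total_all, digits)
  table$percent_excl_MTL <- ifelse(
    table$is_MTL, NA_real_,
    round(100 * table$whole / total_non_mtl, digits))
  table
}
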