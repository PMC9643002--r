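toy_parcellation <- function(grid) {
  lab <- array(0L, grid$shape)
  lab[2:4, 2:4, 2:4] <- 101L
  lab[8:10, 2:4, 2:4] <- 102L
  tab <- data.frame(id = c(101L, 102L), name = c("L_A", "L_B"),
                    hemisphere = "L", is_MTL = c(FALSE, FALSE),
                    is_hippocampus = FALSE, stringsAsFactors = FALSE)
  new_parcellation(lab, tab, grid)
}

test_that("endpoint extraction keeps exactly the mask-terminating subset", {
  grid <- volume_grid(c(12L, 12L, 12L))
  mask <- array(FALSE, grid$shape)
  mask[6:8, 6:8, 6:8] <- TRUE
  strs <- list(
    rbind(c(1, 1, 1), c(3, 3, 3)),            # both endpoints outside
    rbind(c(1, 1, 1), c(6, 6, 6)),            # last point inside -> kept
    rbind(c(6, 6, 6), c(1, 1, 1)),            # first point inside -> kept
    rbind(c(1, 6, 6), c(6.5, 6.5, 6.5), c(11, 6, 6))) # mid-course only
  tg <- structure(list(streamlines = strs, grid = grid), class = "tractogram")
  res <- extract_endpoint_subset(tg, weights = c(1, 2, 3, 4), mask)
  expect_equal(length(res$tractogram), 2L)
  expect_equal(res$weights, c(2, 3))
  expect_error(extract_endpoint_subset(tg, weights = 1:3, mask), "aligned")
})

test_that("split_thirds partitions by half-open intervals", {
  grid <- volume_grid(c(6L, 30L, 6L))
  mask <- array(FALSE, grid$shape)
  mask[3, 1:30, 3] <- TRUE
  field <- array(NA_real_, grid$shape)
  field[3, 1:30, 3] <- seq(0, 1, length.out = 30)
  r <- split_thirds(mask, field)
  expect_equal(sum(r$head) + sum(r$body) + sum(r$tail), sum(mask))
  expect_true(!any((r$head & r$body) | (r$body & r$tail)))
  # a voxel with field exactly 1/3 goes to the body
  f2 <- field
  f2[3, 2, 3] <- 1 / 3
  r2 <- split_thirds(mask, f2)
  expect_true(r2$body[3, 2, 3])
  expect_false(r2$head[3, 2, 3])
  # field 0.20 -> head
  expect_true(r$head[3, 1 + round(0.2 * 29), 3])
  expect_error(split_thirds(mask, field, boundaries = c(0.7, 0.3)),
               "increasing")
  bad <- field
  bad[3, 5, 3] <- NA
  expect_error(split_thirds(mask, bad), "undefined")
})

test_that("straight-tube thirds give a 10/10/10 slab assignment", {
  grid <- volume_grid(c(6L, 34L, 6L))
  cp <- rbind(c(3, 2, 3), c(3, 31.999, 3))
  mask <- array(FALSE, grid$shape)
  mask[3:4, 3:32, 3:4] <- TRUE # 30 slabs along y
  f <- long_axis_field(mask, cp, grid)
  r <- split_thirds(mask, f)
  slab_region <- sapply(3:32, function(y) {
    if (r$head[3, y, 3]) "head" else if (r$body[3, y, 3]) "body" else "tail"
  })
  expect_equal(unname(table(slab_region)[c("head", "body", "tail")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)
})

test_that("assign_parcel uses containment then nearest within radius", {
  grid <- volume_grid(c(12L, 12L, 12L))
  p <- toy_parcellation(grid)
  expect_equal(assign_parcel(c(2, 2, 2), p), 101L)
  # unlabeled voxel adjacent to parcel B at 1 mm
  expect_equal(assign_parcel(c(7, 3, 3), p), 102L)
  # far from any label
  expect_equal(assign_parcel(c(11, 11, 11), p), 0L)
  # 500 random points against the exhaustive oracle
  set.seed(30)
  pts <- cbind(runif(500, 0, 11), runif(500, 0, 11), runif(500, 0, 11))
  got <- assign_parcel(pts, p, search_radius = 2)
  nz <- which(p$labels != 0L, arr.ind = TRUE) - 1L
  ctr <- nz # identity affine
  labs <- p$labels[nz + 1L]
  expected <- vapply(seq_len(500), function(i) {
    v <- floor(pts[i, ] + 0.5)
    if (all(v >= 0) && all(v < 12) && p$labels[v[1] + 1, v[2] + 1, v[3] + 1])
      return(p$labels[v[1] + 1, v[2] + 1, v[3] + 1])
    d <- sqrt(colSums((t(ctr) - pts[i, ])^2))
    if (min(d) <= 2) labs[which.min(d)] else 0L
  }, integer(1))
  expect_identical(got, expected)
})

test_that("connectivity table arithmetic, buckets and conservation", {
  grid <- volume_grid(c(12L, 12L, 12L))
  p <- toy_parcellation(grid)
  mask <- array(FALSE, grid$shape)
  mask[6:8, 6:11, 7:9] <- TRUE # 0-based voxels x 5:7, y 5:10, z 6:8
  field <- array(NA_real_, grid$shape)
  for (y0 in 5:10) field[6:8, y0 + 1, 7:9] <- (y0 - 5) / 5
  regions <- split_thirds(mask, field)
  # head<->A (w 0.5), tail<->A (w 1.0), body<->B (w 2.0), intra (w 0.7)
  strs <- list(rbind(c(6, 5, 7), c(3, 3, 3)),
               rbind(c(6, 10, 7), c(3, 3, 3)),
               rbind(c(6, 8, 7), c(9, 3, 3)),
               rbind(c(6, 5, 7), c(6, 10, 7)))
  tg <- structure(list(streamlines = strs, grid = grid),
                  class = "tractogram")
  tab <- build_connectivity_table(tg, c(0.5, 1, 2, 0.7), p, regions)
  a <- tab[tab$name == "L_A", ]
  b <- tab[tab$name == "L_B", ]
  expect_equal(a$whole, 1.5)
  expect_equal(a$head, 0.5)
  expect_equal(a$tail, 1.0)
  expect_equal(a$body, 0)
  expect_equal(b$whole, 2.0)
  expect_equal(b$body, 2.0)
  expect_equal(attr(tab, "intra_hippocampal"), 0.7)
  expect_equal(attr(tab, "total_weight"),
               sum(tab$whole) + attr(tab, "intra_hippocampal") +
                 attr(tab, "dropped_weight"))
  # per-parcel conservation
  expect_equal(tab$head + tab$body + tab$tail, tab$whole)
  # a streamline with no hippocampal endpoint is a contract violation
  tg_bad <- structure(list(streamlines = c(strs, list(
    rbind(c(1, 1, 1), c(2, 2, 2)))), grid = grid), class = "tractogram")
  expect_error(build_connectivity_table(tg_bad, c(0.5, 1, 2, 0.7, 1), p,
                                        regions), "hippocampal endpoint")
})

test_that("bilateral combination sums hemispheres and conserves columns", {
  tab <- structure(data.frame(
    parcel = 1:5, name = c("L_RSC", "R_RSC", "L_V1", "R_V1", "MST"),
    hemisphere = c("L", "R", "L", "R", "none"),
    is_MTL = FALSE,
    whole = c(3, 4, 2, 1, 5), head = c(1, 1, 1, 0.5, 2),
    body = c(1, 2, 0.5, 0.25, 2), tail = c(1, 1, 0.5, 0.25, 1),
    stringsAsFactors = FALSE),
    class = c("connectivity_table", "data.frame"))
  out <- combine_bilateral(tab)
  expect_equal(out$whole[out$name == "RSC"], 7)
  expect_equal(out$whole[out$name == "MST"], 5)
  expect_equal(sum(out$whole), sum(tab$whole))
  expect_equal(sum(out$head), sum(tab$head))
  out_m <- combine_bilateral(tab, how = "mean")
  expect_equal(out_m$whole[out_m$name == "RSC"], 3.5)
  dup <- tab
  dup$name[2] <- "L_RSC"
  dup$hemisphere[2] <- "L"
  expect_error(combine_bilateral(dup), "duplicate")
})

test_that("percentage columns reproduce printed reference cells", {
  ref <- reference_connectivity_table()
  rec <- recompute_reference_percents(ref)
  expect_true(all(abs(rec$recomputed_percent_all - ref$percent_all)
                  <= 0.01 + 1e-9))
  expect_true(all(abs(rec$recomputed_percent_excl_mtl -
                        ref$percent_excl_mtl) <= 0.01 + 1e-9))
  # spec-level checks of the two implied grand totals
  expect_equal(round(100 * 7673 / attr(rec, "total_excl_mtl"), 2), 10.61)
  expect_equal(round(100 * 5385 / attr(rec, "total_all"), 2), 3.58)
})

test_that("percent_columns sums to 100 and handles MTL exclusion", {
  tab <- structure(data.frame(
    parcel = 1:3, name = c("A", "B", "EC"), hemisphere = "none",
    is_MTL = c(FALSE, FALSE, TRUE),
    whole = c(30, 20, 50), head = c(10, 10, 20), body = c(10, 5, 20),
    tail = c(10, 5, 10), stringsAsFactors = FALSE),
    class = c("connectivity_table", "data.frame"))
  out <- percent_columns(tab)
  expect_equal(sum(out$percent_all), 100, tolerance = 5e-4)
  expect_equal(sum(out$percent_excl_MTL, na.rm = TRUE), 100,
               tolerance = 5e-4)
  expect_equal(out$percent_excl_MTL[1], 60)
  expect_true(is.na(out$percent_excl_MTL[3]))
  # single parcel accounts for all of its own total
  one <- tab[1, ]
  class(one) <- class(tab)
  expect_equal(percent_columns(one)$percent_all, 100)
  zero <- tab
  zero$whole <- 0
  expect_error(percent_columns(zero), "zero")
})

test_that("phantom connectivity recovers the 2:1 ground-truth ratio", {
  ph <- two_bundle_phantom()
  m5 <- amend_to_m5tt(ph$t5, ph$hippocampus_mask, "-z")
  n <- 2000
  tgs <- lapply(1:2, function(i)
    generate_tractogram(n, ph$fod, m5, tracking_params(seed = 50 + i),
                        seeding = "mask", mask = ph$truth$bundle_cores[[i]]))
  comb <- combine_tractograms(tgs[[1]], tgs[[2]])
  sys <- build_density_system(comb, ph$fod, m5)
  w <- fit_weights(sys, max_iters = 500)
  sub <- extract_endpoint_subset(comb, w, ph$hippocampus_mask)
  regions <- split_thirds(ph$hippocampus_mask, ph$long_axis)
  tab <- build_connectivity_table(sub$tractogram, sub$weights,
                                  ph$parcellation, regions)
  wa <- tab$whole[tab$name == "L_A"]
  wb <- tab$whole[tab$name == "L_B"]
  expect_gt(wa / wb, 1.8)
  expect_lt(wa / wb, 2.2)
  # ranking matches ground-truth densities
  expect_gt(wa, wb)
})
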