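test_that("empty-bundle config gives a zero FOD and background parcellation", {
  ph <- build_phantom(phantom_config(bundles = list()))
  expect_true(all(ph$fod$coeff == 0))
  expect_true(all(ph$parcellation$labels == 0L))
  expect_gt(sum(ph$hippocampus_mask), 0)
})

test_that("phantom generation is deterministic", {
  a <- build_phantom(phantom_config())
  b <- build_phantom(phantom_config())
  expect_identical(a$t5$data, b$t5$data)
  expect_identical(a$fod$coeff, b$fod$coeff)
  expect_identical(a$parcellation$labels, b$parcellation$labels)
  expect_identical(a$long_axis, b$long_axis)
})

test_that("tissue partial volumes are conserved", {
  ph <- default_phantom()
  sums <- rowSums(matrix(ph$t5$data, ncol = 5L))
  expect_true(all(sums >= 0 & sums <= 1 + 1e-6))
  # inside the head (brain incl. CSF shell) the sum is exactly 1
  shp <- ph$grid$shape
  headreg <- array(FALSE, shp)
  headreg[2:(shp[1] - 1), 2:(shp[2] - 1), 2:(shp[3] - 1)] <- TRUE
  expect_true(all(abs(rowSums(matrix(ph$t5$data, ncol = 5))[headreg] - 1)
                  < 1e-6))
})

test_that("bundle tubes carry WM and the declared FOD energy ratios", {
  cfg <- phantom_config(bundles = list(
    bundle_spec(11L, "L_P", "head", density = 2,
                control_points = rbind(c(8, 10, 5), c(8, 10, 16))),
    bundle_spec(12L, "L_Q", "head", density = 1,
                control_points = rbind(c(30, 10, 5), c(30, 10, 16)))))
  ph <- build_phantom(cfg)
  hip_or_sheet <- ph$hippocampus_mask | ph$sheet_mask
  for (i in 1:2) {
    tube <- ph$truth$bundle_tubes[[i]]
    wm_part <- ph$t5$data[, , , 3][tube & !hip_or_sheet &
                                     !ph$truth$bundle_tubes[[3 - i]]]
    # outside parcel blocks the tube is white matter
    expect_gt(mean(wm_part >= 0.5), 0.6)
  }
  # l=0 coefficient (density) ratio matches the synthesize_fod oracle 2:1
  core1 <- ph$truth$bundle_cores[[1]] & !ph$truth$bundle_cores[[2]]
  core2 <- ph$truth$bundle_cores[[2]] & !ph$truth$bundle_cores[[1]]
  c0 <- ph$fod$coeff[, , , 1]
  r <- median(c0[core1]) / median(c0[core2])
  expect_equal(r, 2, tolerance = 1e-6)
  expect_equal(median(c0[core1]),
               synthesize_fod(list(list(direction = c(0, 0, 1),
                                        density = 2)))[1],
               tolerance = 1e-6)
})

test_that("overlapping bundles give multi-lobed FODs, not errors", {
  cfg <- phantom_config(bundles = list(
    bundle_spec(11L, "L_P", "head", density = 1,
                control_points = rbind(c(10, 20, 5), c(10, 20, 16))),
    bundle_spec(12L, "L_Q", "head", density = 1,
                control_points = rbind(c(5, 20, 10), c(16, 20, 10)))))
  ph <- build_phantom(cfg)
  cross <- ph$truth$bundle_tubes[[1]] & ph$truth$bundle_tubes[[2]]
  expect_gt(sum(cross), 0)
  lin <- which(cross)[1]
  v <- arrayInd(lin, ph$grid$shape) - 1L
  coef <- ph$fod$coeff[v[1] + 1, v[2] + 1, v[3] + 1, ]
  az <- fod_amplitude(coef, c(0, 0, 1))
  ax <- fod_amplitude(coef, c(1, 0, 0))
  ad <- fod_amplitude(coef, c(1, 0, 1) / sqrt(2))
  expect_gt(az, 3 * ad)
  expect_gt(ax, 3 * ad)
})

test_that("ground truth is consistent with the parcellation and thirds", {
  ph <- default_phantom()
  regions <- split_thirds(ph$hippocampus_mask, ph$long_axis)
  for (i in seq_len(nrow(ph$truth$bundles))) {
    b <- ph$truth$bundles[i, ]
    expect_true(b$parcel %in% ph$parcellation$table$id)
    expect_gt(sum(ph$parcellation$labels == b$parcel), 0)
    # the parcel block touches the bundle's far end
    pth <- ph$truth$bundle_paths[[i]]
    v0 <- drop(hippotrack:::containing_voxel(ph$grid, pth[1, ]))
    expect_equal(ph$parcellation$labels[v0[1] + 1, v0[2] + 1, v0[3] + 1],
                 b$parcel)
    # the bundle's hippocampal end lies in the declared segment
    pend <- pth[nrow(pth), ]
    vend <- drop(hippotrack:::containing_voxel(ph$grid, pend))
    expect_true(regions[[b$segment]][vend[1] + 1, vend[2] + 1, vend[3] + 1])
  }
})

test_that("the obstructing sheet sits immediately inferior to the mask", {
  ph <- default_phantom()
  expect_gt(sum(ph$sheet_mask), 0)
  expect_true(!any(ph$sheet_mask & ph$hippocampus_mask))
  # every sheet voxel has a hippocampus voxel directly above (+z)
  idx <- which(ph$sheet_mask, arr.ind = TRUE)
  above <- idx
  above[, 3] <- above[, 3] + 1L
  expect_true(all(ph$hippocampus_mask[above]))
  # sheet voxels are cortical GM in the unamended 5TT
  expect_true(all(ph$t5$data[, , , 1][ph$sheet_mask] == 1))
  expect_true(all(ph$t5$data[, , , 1][ph$hippocampus_mask] == 1))
})

test_that("long_axis_field spans [0,1] and matches analytic arc length", {
  # straight 30 mm tube along +y
  grid <- volume_grid(c(12L, 40L, 12L))
  cp <- rbind(c(6, 4, 6), c(6, 34, 6))
  samples <- hippotrack:::sample_centreline(cp)
  mask <- hippotrack:::tube_mask(grid, samples, 2.5)
  f <- long_axis_field(mask, cp, grid)
  expect_equal(min(f, na.rm = TRUE), 0)
  expect_equal(max(f, na.rm = TRUE), 1)
  expect_true(all(!is.na(f[mask])))
  # voxel 10 mm from the anterior tip: fraction 1/3 up to quantisation
  v <- c(6, 14, 6) # world == index for the identity grid
  expect_equal(f[v[1] + 1, v[2] + 1, v[3] + 1], 1 / 3, tolerance = 0.04)
  # monotone along the centreline
  along <- sapply(4:34, function(y) f[7, y + 1, 7])
  expect_true(all(diff(along) >= -1e-9))
  # voxels too far from the centreline raise an error
  mask_bad <- mask
  mask_bad[1, 1, 1] <- TRUE
  expect_error(long_axis_field(mask_bad, cp, grid), "max_distance")
})

test_that("phantom config validation rejects malformed input", {
  expect_error(phantom_config(lmax = 7), "even")
  expect_error(phantom_config(inferior_axis = "down"), "inferior_axis")
  expect_error(bundle_spec(1L, "X", "middle"), "arg")
  expect_error(bundle_spec(1L, "X", "head", density = -1))
})
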