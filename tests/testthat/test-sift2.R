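straight_tractogram <- function(grid, xs, y = 10, z = 10, step = 0.5,
                                from = 2, to = 18) {
  strs <- lapply(xs, function(x) {
    yy <- seq(from, to, by = step)
    cbind(x, yy, z)
  })
  tg <- list(streamlines = strs, grid = grid, params = NULL)
  class(tg) <- "tractogram"
  tg
}

test_that("polyline-voxel lengths match simple geometry and a sampling oracle", {
  grid <- volume_grid(c(20L, 20L, 20L))
  # one axis-aligned streamline through voxel centres: 1 mm per voxel
  tg <- straight_tractogram(grid, xs = 10, from = 2, to = 18)
  dummy_fod <- fod_field(array(c(rep(1, prod(grid$shape)),
                                 rep(0, prod(grid$shape) * 44)),
                               c(grid$shape, 45)), grid, 8)
  d <- array(0, c(grid$shape, 5))
  d[, , , 3] <- 1
  t5 <- tissue5tt(d, grid)
  sys <- build_density_system(tg, dummy_fod, t5)
  lens <- sys$L[, 1]
  interior <- lens[lens > 1e-9]
  # voxels traversed centrally measure exactly 1 mm (ends truncated)
  expect_true(all(abs(interior[interior > 0.6] - 1) < 1e-9))
  # random oblique streamline vs the dense-sampling oracle
  set.seed(20)
  pts <- cbind(runif(4, 4, 16), runif(4, 4, 16), runif(4, 4, 16))
  tg2 <- list(streamlines = list(pts), grid = grid)
  class(tg2) <- "tractogram"
  trip <- hippotrack:::cpp_voxel_lengths(tg2$streamlines,
                                         hippotrack:::world2vox34(grid),
                                         grid$shape)
  ora <- oracle_voxel_lengths(pts, grid, n_samp = 200000)
  got <- setNames(trip$length, trip$voxel)
  lin_ora <- 1 + ora$voxel[, 1] + grid$shape[1] *
    (ora$voxel[, 2] + grid$shape[2] * ora$voxel[, 3])
  for (i in seq_along(lin_ora)) {
    g <- got[as.character(lin_ora[i])]
    g <- if (is.na(g)) 0 else g
    expect_lt(abs(g - ora$length[i]), 1e-3)
  }
  expect_error(build_density_system(
    structure(list(streamlines = list(), grid = grid), class = "tractogram"),
    dummy_fod, t5), "empty")
})

test_that("a perfectly matched system keeps weights at 1", {
  grid <- volume_grid(c(20L, 20L, 20L))
  tg <- straight_tractogram(grid, xs = c(8, 10, 12))
  # build D to equal the unweighted streamline density exactly
  d <- array(0, c(grid$shape, 5))
  d[, , , 3] <- 1
  t5 <- tissue5tt(d, grid)
  dummy_fod <- fod_field(array(c(rep(1, prod(grid$shape)),
                                 rep(0, prod(grid$shape) * 44)),
                               c(grid$shape, 45)), grid, 8)
  sys <- build_density_system(tg, dummy_fod, t5)
  cov <- as.numeric(sys$L %*% rep(1, 3))
  sys$D <- cov # unit weights with mu = 1 fit exactly
  w <- fit_weights(sys, lambda = 0.01)
  expect_equal(as.numeric(w), rep(1, 3), tolerance = 1e-3)
  expect_equal(attr(w, "mu"), 1, tolerance = 1e-9)
})

test_that("huge regularisation drives all weights to 1", {
  run <- small_run()
  sys <- build_density_system(run$combined, run$phantom$fod, run$m5tt)
  w <- fit_weights(sys, lambda = 1e8)
  expect_true(all(abs(as.numeric(w) - 1) < 1e-2))
})

test_that("objective is monotone and lambda must be non-negative", {
  run <- small_run()
  sys <- build_density_system(run$combined, run$phantom$fod, run$m5tt)
  w <- fit_weights(sys)
  tr <- attr(w, "objective")
  expect_true(all(diff(tr) <= 1e-9 * tr[1]))
  expect_error(fit_weights(sys, lambda = -1), "lambda")
  bad <- sys
  bad$D <- bad$D * 0
  expect_error(fit_weights(bad), "zero")
})

test_that("scaling the density target rescales mu and not the weights", {
  run <- small_run()
  sys <- build_density_system(run$combined, run$phantom$fod, run$m5tt)
  w1 <- fit_weights(sys, max_iters = 300)
  sys2 <- sys
  sys2$D <- sys$D * 3
  w2 <- fit_weights(sys2, max_iters = 300)
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-4)
  expect_equal(attr(w2, "mu") * 3, attr(w1, "mu"), tolerance = 1e-6)
})

test_that("lambda = 0 fitted densities agree with a generic NNLS solver", {
  ph <- two_bundle_phantom()
  m5 <- amend_to_m5tt(ph$t5, ph$hippocampus_mask, "-z")
  tgs <- lapply(1:2, function(i)
    generate_tractogram(100, ph$fod, m5, tracking_params(seed = 30 + i),
                        seeding = "mask", mask = ph$truth$bundle_cores[[i]]))
  comb <- combine_tractograms(tgs[[1]], tgs[[2]])
  sys <- build_density_system(comb, ph$fod, m5)
  w <- fit_weights(sys, lambda = 0, max_iters = 4000, tol = 1e-14)
  fitted <- as.numeric(sys$L %*% as.numeric(w)) / attr(w, "mu")
  A <- as.matrix(sys$L)
  nn <- pracma::lsqnonneg(A, sys$D)
  fitted_oracle <- drop(A %*% nn$x)
  rel <- sqrt(sum((fitted - fitted_oracle)^2)) / sqrt(sum(sys$D^2))
  expect_lt(rel, 0.01)
})

test_that("2:1 fibre densities are recovered by per-bundle weight sums", {
  ph <- two_bundle_phantom()
  m5 <- amend_to_m5tt(ph$t5, ph$hippocampus_mask, "-z")
  n <- 2000 # scaled-down variant of the full acceptance experiment
  tgs <- lapply(1:2, function(i)
    generate_tractogram(n, ph$fod, m5, tracking_params(seed = 40 + i),
                        seeding = "mask", mask = ph$truth$bundle_cores[[i]]))
  comb <- combine_tractograms(tgs[[1]], tgs[[2]])
  sys <- build_density_system(comb, ph$fod, m5)
  w <- fit_weights(sys, max_iters = 500)
  ratio <- sum(w[seq_len(n)]) / sum(w[n + seq_len(n)])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})
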