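test_that("sample_direction honours the cutoff and the cone", {
  p <- tracking_params(max_trials = 200)
  # amplitude below cutoff everywhere -> no direction
  tiny <- synthesize_fod(list(list(direction = c(0, 0, 1), density = 0.01)))
  set.seed(1)
  expect_null(sample_direction(tiny, c(0, 0, 1), p))
  # lobe perpendicular to the previous direction, 45-degree cone -> none
  lobe <- synthesize_fod(list(list(direction = c(1, 0, 0), density = 1)))
  set.seed(2)
  expect_null(sample_direction(lobe, c(0, 0, 1), p))
})

test_that("sampled directions concentrate on the lobe peak", {
  lobe <- synthesize_fod(list(list(direction = c(0, 0, 1), density = 1)))
  p <- tracking_params()
  set.seed(3)
  n <- 0
  acc <- c(0, 0, 0)
  for (i in 1:10000) {
    d <- sample_direction(lobe, c(0, 0, 1), p)
    if (!is.null(d)) {
      acc <- acc + d
      n <- n + 1
    }
  }
  expect_gt(n, 5000)
  mean_dir <- acc / sqrt(sum(acc^2))
  # mean accepted direction within 5 degrees of the lobe peak
  expect_gt(sum(mean_dir * c(0, 0, 1)), cos(5 * pi / 180))
})

test_that("track_from_seed applies the ACT rules", {
  ph <- default_phantom()
  m5 <- default_m5tt()
  # CSF shell voxel -> rejected with no propagation
  res <- track_from_seed(c(1, 20, 16), ph$fod, ph$t5,
                         tracking_params(seed = 4))
  expect_equal(res$status, "rejected_csf")
  # seed outside the field of view errors
  expect_error(track_from_seed(c(-10, 0, 0), ph$fod, ph$t5), "field of view")
  # seed mid-bundle on the m5TT: accepted, endpoints near GM / no-priors
  pth <- ph$truth$bundle_paths[[1]]
  midpt <- pth[which.min(abs(pth[, 3] - 12)), ]
  res <- track_from_seed(midpt, ph$fod, m5, tracking_params(seed = 5))
  expect_equal(res$status, "accepted")
  states <- act_state_at(m5, res$points[c(1, nrow(res$points)), ])$state
  expect_true(all(states %in% c("CORTICAL_GM", "SUBCORTICAL_GM",
                                "NO_PRIORS")))
})

test_that("a short WM stub between GM blocks is rejected as too short", {
  grid <- volume_grid(c(12L, 9L, 9L))
  d <- array(0, c(12, 9, 9, 5))
  d[, , , 4] <- 1 # CSF everywhere
  d[4:8, 4:6, 4:6, 4] <- 0
  d[4:8, 4:6, 4:6, 3] <- 1 # corridor with ~3 mm of WM between GM caps
  d[c(4, 8), 4:6, 4:6, 3] <- 0
  d[c(4, 8), 4:6, 4:6, 1] <- 1 # GM caps
  t5s <- tissue5tt(d, grid)
  coef <- array(0, c(12, 9, 9, sh_ncoef(8)))
  lob <- synthesize_fod(list(list(direction = c(1, 0, 0), density = 1)))
  for (k in seq_along(lob)) coef[4:8, 4:6, 4:6, k] <- lob[k]
  fod_stub <- fod_field(coef, grid, 8)
  res <- track_from_seed(c(5, 4, 4), fod_stub, t5s, tracking_params(seed = 6))
  expect_equal(res$status, "rejected_short")
})

test_that("accepted streamlines satisfy step, length and CSF invariants", {
  ph <- default_phantom()
  m5 <- default_m5tt()
  p <- tracking_params(seed = 7)
  tg <- generate_tractogram(300, ph$fod, m5, p, seeding = "mask",
                            mask = ph$hippocampus_mask)
  expect_equal(length(tg), 300)
  step <- 0.5 * min(ph$grid$voxel_size)
  for (m in tg$streamlines[1:50]) {
    d <- sqrt(rowSums(diff(m)^2))
    expect_true(all(abs(d - step) < 1e-5))
    len <- sum(d)
    expect_gte(len, p$min_length - 1e-9)
    expect_lte(len, p$max_length + 1e-9)
  }
  # no accepted point has CSF fraction > 0.5
  pts <- do.call(rbind, tg$streamlines)
  fr <- act_state_at(m5, pts)$fractions
  expect_true(all(fr[, "csf"] <= 0.5 + 1e-9))
  # endpoint plausibility: >= 95% of endpoints in GM, no-priors or border
  ep <- streamline_endpoints(tg)
  sta <- act_state_at(m5, ep)
  ok <- sta$state %in% c("CORTICAL_GM", "SUBCORTICAL_GM", "NO_PRIORS",
                         "OUTSIDE")
  expect_gte(mean(ok), 0.95)
})

test_that("tractogram generation is reproducible and budget-limited", {
  ph <- default_phantom()
  m5 <- default_m5tt()
  expect_equal(length(generate_tractogram(0, ph$fod, m5)), 0L)
  p <- tracking_params(seed = 8)
  a <- generate_tractogram(50, ph$fod, m5, p, seeding = "mask",
                           mask = ph$hippocampus_mask)
  b <- generate_tractogram(50, ph$fod, m5, p, seeding = "mask",
                           mask = ph$hippocampus_mask)
  expect_identical(a$streamlines, b$streamlines)
  # impossible request exhausts the budget with a warning, not an error
  p2 <- tracking_params(seed = 9, max_attempts_per_seed = 5)
  expect_warning(
    tg <- generate_tractogram(500, ph$fod, ph$t5, p2, seeding = "mask",
                              mask = ph$hippocampus_mask),
    "budget")
  expect_lt(length(tg), 500)
  expect_true(tg$budget_exhausted)
})

test_that("most hippocampus-seeded accepted streamlines leave the mask", {
  ph <- default_phantom()
  m5 <- default_m5tt()
  tg <- generate_tractogram(1000, ph$fod, m5, tracking_params(seed = 10),
                            seeding = "mask", mask = ph$hippocampus_mask)
  inm <- hippotrack:::endpoint_in_mask(tg, ph$hippocampus_mask)
  expect_gt(mean(!inm$both), 0.5)
})
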