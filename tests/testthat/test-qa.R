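hu_vol <- function(values, n = NULL) {
  if (is.null(n)) n <- nrow(values)
  volume(values, reconGrid(n, 1.75), unit = "hu")
}

roi_row <- function(cx = 0, cy = 0, r = 20) {
  data.frame(name = "roi", cx_mm = cx, cy_mm = cy, r_mm = r,
             role = "insert", material = "water")
}

test_that("ROI statistics use the population convention on center-in-disk voxels", {
  n <- 64
  v <- hu_vol(matrix(100, n, n))
  st <- roiStats(v, roi_row())
  expect_equal(st$mean_hu, 100)
  expect_equal(st$sd_hu, 0)
  expect_gt(st$voxel_count, 1)
  # two-value population: mean 1, sd 1 (not the sample sd of sqrt(2))
  vals <- matrix(0, n, n); vals[1:2] <- c(0, 2)
  grid <- reconGrid(n, 1.75)
  st2 <- decbct:::.mask_stats(vals, matrix(seq_len(n * n) <= 2, n, n))
  expect_equal(st2$mean_hu, 1); expect_equal(st2$sd_hu, 1)
  # sampling oracle: Gaussian field statistics recovered within 3 s.e.
  set.seed(3)
  g <- hu_vol(matrix(rnorm(n * n, 50, 10), n, n))
  big <- roiStats(g, roi_row(r = 50))
  m <- big$voxel_count
  expect_lt(abs(big$mean_hu - 50), 3 * 10 / sqrt(m))
  expect_lt(abs(big$sd_hu - 10), 3 * 10 / sqrt(2 * m))
  expect_error(roiStats(g, roi_row(cx = 500)), "empty ROI")
  vmu <- volume(matrix(0.2, n, n), reconGrid(n, 1.75), unit = "mu")
  expect_error(roiStats(vmu, roi_row()), "HU volume")
})

test_that("CNR follows the pooled-noise formula and its invariances", {
  s <- function(m, sd) list(mean_hu = m, sd_hu = sd)
  expect_equal(cnr(s(100, 10), s(0, 10)), 10)
  expect_equal(cnr(s(50, 6), s(20, 8)), 30 / sqrt(50))
  expect_equal(cnr(s(7, 3), s(7, 9)), 0)
  expect_error(cnr(s(1, 0), s(0, 0)), "degenerate")
  # invariant under adding a constant and under positive rescaling of the
  # image (contrast and noise scale together)
  expect_equal(cnr(s(150, 6), s(120, 8)), cnr(s(50, 6), s(20, 8)))
  expect_equal(cnr(s(100, 12), s(40, 16)), cnr(s(50, 6), s(20, 8)))
})

test_that("rCNR is a per-insert ratio with zero-reference exclusion", {
  v <- c(a = 2, b = 4, c = -3)
  r <- c(a = 2, b = 2, c = -3)
  out <- rcnr(v, r)
  expect_equal(unname(out$per_insert), c(1, 2, 1))
  expect_equal(out$mean, 4 / 3)
  # self-comparison: all ones
  self <- rcnr(v, v)
  expect_equal(unname(self$per_insert), c(1, 1, 1))
  expect_equal(self$mean, 1); expect_equal(self$sd, 0)
  # doubled CNR everywhere: mean 2, sd 0
  dbl <- rcnr(2 * v, v)
  expect_equal(dbl$mean, 2); expect_equal(dbl$sd, 0)
  # contrast inversion preserves sign of the ratio
  expect_equal(unname(rcnr(c(x = -2), c(x = 2))$per_insert), -1)
  expect_warning(out0 <- rcnr(c(a = 1, b = 1), c(a = 0, b = 2)), "zero reference")
  expect_equal(out0$mean, 0.5)
})

test_that("HU accuracy compares ROI means against theoretical values", {
  rois <- defaultRois()
  grid <- reconGrid(128, 1.75)
  lab <- rasterize(defaultCatphan(), grid)
  truth <- matrix(0, 128, 128)
  for (m in unique(as.vector(lab))) truth[lab == m] <- theoreticalHu(m, 60)
  v <- volume(truth, grid, unit = "hu")
  acc <- huAccuracy(v, rois, 60)
  # rasterized truth reproduces itself (only raster edge effects, none inside
  # the 60%-radius ROIs)
  expect_lt(acc$max_abs, 1e-9)
  # constant offset shifts the mean exactly
  v20 <- volume(truth + 20, grid, unit = "hu")
  acc20 <- huAccuracy(v20, rois, 60)
  expect_equal(acc20$mean, 20, tolerance = 1e-9)
  expect_equal(acc20$sd, 0, tolerance = 1e-9)
})

test_that("HU uniformity is the center-minus-periphery difference and antisymmetric", {
  n <- 128
  grid <- reconGrid(n, 1.75)
  rois <- defaultRois()
  uni <- volume(matrix(42, n, n), grid, unit = "hu")
  expect_equal(huUniformity(uni, rois), 0)
  # build an image with prescribed ROI means: center 10, peripherals 2,4,6,8
  vals <- matrix(0, n, n)
  per <- rois[rois$role == "uniformity_peripheral", ]
  cen <- rois[rois$role == "uniformity_center", ]
  put <- function(vals, roi, x) { vals[decbct:::.roi_mask(grid, roi)] <- x; vals }
  vals <- put(vals, cen[1, ], 10)
  for (i in 1:4) vals <- put(vals, per[i, ], 2 * i)
  v <- volume(vals, grid, unit = "hu")
  expect_equal(huUniformity(v, rois), 5)
  # antisymmetry: exchanging the center and periphery levels negates the value
  vals_a <- put(matrix(0, n, n), cen[1, ], 12)
  for (i in 1:4) vals_a <- put(vals_a, per[i, ], 3)
  vals_b <- put(matrix(0, n, n), cen[1, ], 3)
  for (i in 1:4) vals_b <- put(vals_b, per[i, ], 12)
  expect_equal(huUniformity(volume(vals_a, grid, unit = "hu"), rois),
               -huUniformity(volume(vals_b, grid, unit = "hu"), rois))
  bad <- rois[rois$role != "uniformity_center", ]
  expect_error(huUniformity(v, bad), "exactly 1 center")
})

test_that("the assembled report is internally consistent", {
  sim <- de_noisy_128()
  rois <- defaultRois()
  v <- synthesizeFast(sim$images, 60)
  rep_self <- buildReport(v, v, rois)
  expect_equal(rep_self$rcnr_mean, 1)
  expect_equal(rep_self$uniformity_vmi, rep_self$uniformity_reference)
  expect_true(all(is.finite(unlist(rep_self$cnr_vmi))))
  # summary statistics recompute from the per-insert values
  keep <- !is.na(rep_self$rcnr_per_insert)
  expect_equal(rep_self$rcnr_mean, mean(rep_self$rcnr_per_insert[keep]))
  expect_equal(rep_self$hu_accuracy$mean, mean(rep_self$hu_accuracy$per_insert$delta_hu))
})
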