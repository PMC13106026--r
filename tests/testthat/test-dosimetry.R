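test_that("linear calibration fits exactly on collinear data and recovers noisy slopes", {
  m <- fitLinear(list(x = c(0, 1), y = c(0, 2)))
  expect_equal(m$slope, 2); expect_equal(m$intercept, 0)
  expect_equal(m$r_squared, 1)
  coll <- fitLinear(list(x = 1:5, y = 3 * (1:5) - 7))
  expect_equal(coll$r_squared, 1)
  # Monte-Carlo slope recovery within 3 standard errors
  set.seed(17)
  x <- seq(100, 1700, length.out = 50)
  y <- 0.08 * x + rnorm(50, 0, 0.5)
  fit <- fitLinear(list(x = x, y = y))
  se <- 0.5 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - 0.08), 3 * se)
  expect_error(fitLinear(list(x = 1, y = 1)), ">= 2")
  expect_error(fitLinear(list(x = c(2, 2), y = c(1, 3))), "zero variance")
})

test_that("air kerma from charge applies calibration and corrections", {
  cal <- chamberCalibration(nk = 5e7)
  expect_equal(kairFromCharge(2e-9, cal), 100)          # 0.1 Gy = 100 mGy
  expect_equal(kairFromCharge(4e-9, cal), 200)          # linear in charge
  # reference temperature/pressure give a ptp factor of exactly 1
  expect_equal(decbct:::.ptp_correction(22, 101.325), 1)
  warm <- chamberCalibration(5e7, temperature = 32)
  expect_gt(kairFromCharge(2e-9, warm), 100)
  expect_error(kairFromCharge(0, cal), "positive")
})

test_that("kerma estimation is linear and flags extrapolation", {
  m <- structure(list(slope = 2, intercept = 1, r_squared = 1, n_points = 5,
                      x_range = c(5, 100)), class = "linear_model")
  est <- estimateKair(m, 10)
  expect_equal(est$kair_mGy, 21)
  expect_false(est$extrapolated)
  expect_true(estimateKair(m, 2)$extrapolated)
  # exact linearity: estimate(a x) - b = a (estimate(x) - b)
  a <- 3.7; x <- 40
  expect_equal(estimateKair(m, a * x)$kair_mGy - m$intercept,
               a * (estimateKair(m, x)$kair_mGy - m$intercept))
  expect_error(estimateKair(m, -1), "non-negative")
})

test_that("refit of the 140 kVp kerma model reproduces the validation measurements", {
  model <- kairModel(140)
  tab <- kairValidationTable()
  tab <- tab[tab$kvp == 140, ]
  pred <- estimateKair(model, tab$cumulative_mAs)$kair_mGy
  # every measured protocol predicted within 6% (worst case at the lowest mAs)
  expect_true(all(abs(pred - tab$measured_mGy) / tab$measured_mGy < 0.06))
  # the reference protocol itself within 1% of the printed measurement
  at_ref <- estimateKair(model, 1688)$kair_mGy
  expect_lt(abs(at_ref - 135.2) / 135.2, 0.01)
  expect_gt(model$r_squared, 0.999)
})

test_that("combined dual-energy dose and relative percentages follow the printed arithmetic", {
  d <- combinedDose(67, 67, 134)
  expect_equal(d$combined, 134); expect_equal(d$relative_percent, 100)
  expect_equal(combinedDose(0, 50, 50)$relative_percent, 100)
  expect_equal(combinedDose(40, 41, 134)$relative_percent, 60)
  # symmetry in the two energy arguments
  expect_equal(combinedDose(10, 30, 50)$combined, combinedDose(30, 10, 50)$combined)
  expect_error(combinedDose(1, 1, 0), "positive")
})

test_that("percent differences are signed and reported to one decimal", {
  expect_equal(percentDifference(29.0, 27.4), 5.8)
  expect_equal(percentDifference(5.8, 5.7), 1.8)
  expect_equal(percentDifference(13.3, 13.3), 0)
  expect_lt(percentDifference(27.4, 29.0), 0)
  expect_error(percentDifference(1, 0), "positive")
})

test_that("weighted dose index uses the 1/3 + 2/3 convention", {
  expect_equal(cbdiw(10, rep(20, 4)), 10 / 3 + 40 / 3 * 1)
  expect_equal(cbdiw(10, rep(20, 4)), 50 / 3)
  expect_equal(cbdiw(7, rep(7, 4)), 7)
  expect_equal(cbdiw(12, c(10, 10, 14, 14)), 12)
  expect_error(cbdiw(10, c(1, 2, 3)), "4 peripheral")
})

test_that("body-to-head phantom conversion applies the 2.34 factor", {
  expect_equal(convertPhantom(10), 23.4)
  expect_equal(convertPhantom(0), 0)
  expect_equal(convertPhantom(1), 2.34)
})

test_that("dose-index surrogate correlation requires pairing and recovers slopes", {
  kair <- data.frame(protocol = 1:7, kair = c(5, 10, 20, 35, 60, 95, 135))
  cbdi <- data.frame(protocol = 1:7, cbdi = 1.8 * kair$kair)
  m <- correlateSurrogate(cbdi, kair)
  expect_equal(m$r_squared, 1)
  expect_equal(m$slope, 1.8, tolerance = 1e-12)
  # noisy slope recovery within 3 se
  set.seed(8)
  cbdi2 <- data.frame(protocol = 1:7, cbdi = 1.8 * kair$kair + rnorm(7, 0, 1))
  m2 <- correlateSurrogate(cbdi2, kair)
  se <- 1 / sqrt(sum((kair$kair - mean(kair$kair))^2))
  expect_lt(abs(m2$slope - 1.8), 3 * se)
  expect_error(correlateSurrogate(cbdi[1:5, ], kair), "paired")
})

test_that("run dose estimates reproduce the published relative dose tiers", {
  # matched-dose run: 4046/833 mAs sums to ~100% of the reference kerma
  d2 <- runDoseEstimate(4046, 833)
  expect_equal(d2$relative_percent, 100)
  # reduced-dose run: 2440/483 mAs lands at 60%
  d8 <- runDoseEstimate(2440, 483)
  expect_equal(d8$relative_percent, 60)
  expect_true(d2$extrapolation_flag)   # 4046 mAs is beyond the fitted range
})
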