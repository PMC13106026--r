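test_that("forward model is exact for monoenergetic spectra and monotone in thickness", {
  grid <- energyGrid()
  mono <- function(e) structure(list(kvp = 150, energies = grid,
                                     fluence = as.numeric(grid == e),
                                     filtration_mm_al = 0), class = "spectrum")
  sys <- basisSystem(mono(50), mono(100))
  L <- forwardDual(c(0, 2), c(0, 10), sys)
  expect_equal(L[1, ], c(L_low = 0, L_high = 0))
  expect_equal(unname(L[2, 1]),
               linearAttenuation("aluminum", 50) * 2 +
                 linearAttenuation("pmma", 50) * 10, tolerance = 1e-12)
  expect_equal(unname(L[2, 2]),
               linearAttenuation("aluminum", 100) * 2 +
                 linearAttenuation("pmma", 100) * 10, tolerance = 1e-12)
  # monoenergetic pair: solver matches the closed-form 2x2 linear inverse
  M <- rbind(c(linearAttenuation("aluminum", 50), linearAttenuation("pmma", 50)),
             c(linearAttenuation("aluminum", 100), linearAttenuation("pmma", 100)))
  tt <- solve(M, c(L[2, 1], L[2, 2]))
  sol <- solveRay(L[2, 1], L[2, 2], sys)
  expect_equal(unname(c(sol$t_al, sol$t_pmma)), unname(tt), tolerance = 1e-8)

  # polyenergetic forward is strictly increasing in each basis thickness
  sysd <- defaultBasisSystem()
  for (col in 1:2) {
    La <- forwardDual(seq(0, 4, 0.5), rep(5, 9), sysd)[, col]
    Lp <- forwardDual(rep(1, 9), seq(0, 30, length.out = 9), sysd)[, col]
    expect_true(all(diff(La) > 0) && all(diff(Lp) > 0))
  }
  # near-identical spectra are rejected as ill-conditioned
  expect_error(basisSystem(mono(60), mono(60)), "condition")
})

test_that("noiseless round trip recovers thicknesses to 1e-5 cm over the full range", {
  sys <- defaultBasisSystem()
  g <- expand.grid(t_al = seq(0, 4, length.out = 20),
                   t_pmma = seq(0, 30, length.out = 20))
  L <- forwardDual(g$t_al, g$t_pmma, sys)
  sol <- solveRay(L[, 1], L[, 2], sys)
  expect_true(all(sol$converged))
  expect_lt(max(abs(sol$t_al - g$t_al)), 1e-5)
  expect_lt(max(abs(sol$t_pmma - g$t_pmma)), 1e-5)
  # (0,0) stays at (0,0)
  z <- solveRay(0, 0, sys)
  expect_equal(c(z$t_al, z$t_pmma), c(0, 0), tolerance = 1e-9)
})

test_that("sinogram decomposition matches ground-truth chords on a pure-PMMA cylinder", {
  spec <- phantomSpec(100, "pmma", name = "pmma_cylinder")
  g <- small_geom()
  prot80 <- protocolFromMas(80, 1000, 3)
  prot140 <- protocolFromMas(140, 500, 3)
  p80 <- acquire(spec, prot80, g, noise = FALSE)
  p140 <- acquire(spec, prot140, g, noise = FALSE)
  bs <- decompose(p80, p140)
  chords <- raytrace(spec, g, 0)[, "pmma"]
  expect_lt(max(abs(bs$t_al)), 0.05)
  expect_equal(bs$t_pmma[1, ], unname(chords), tolerance = 0.01)
  # decompose-then-forward reproduces both measured log sinograms
  L <- forwardDual(as.vector(bs$t_al), as.vector(bs$t_pmma))
  expect_lt(max(abs(L[, 1] - as.vector(p80$line_integrals))), 1e-6)
  expect_lt(max(abs(L[, 2] - as.vector(p140$line_integrals))), 1e-6)
  expect_equal(bs$frac_nonconverged, 0)
  # angle mismatch is refused
  p140b <- p140; p140b$angles <- p140b$angles + 1
  expect_error(decompose(p80, p140b), "mismatch")
})

test_that("air scans decompose to near-zero thicknesses", {
  spec <- phantomSpec(100, "air", name = "air_only")
  g <- small_geom()
  p80 <- acquire(spec, protocolFromMas(80, 1000, 3), g, noise = FALSE)
  p140 <- acquire(spec, protocolFromMas(140, 500, 3), g, noise = FALSE)
  bs <- decompose(p80, p140)
  expect_lt(max(abs(bs$t_al)), 0.01)
  expect_lt(max(abs(bs$t_pmma)), 0.05)
})

test_that("Poisson noise induces anti-correlated basis-thickness errors", {
  sys <- defaultBasisSystem()
  # one fixed ray through 1 cm Al + 15 cm PMMA, many noise realizations
  L_true <- forwardDual(1, 15, sys)
  sp80 <- defaultSpectrum(80); sp140 <- defaultSpectrum(140)
  n <- 400
  I0_80 <- 2e5; I0_140 <- 2e5
  set.seed(99)
  noisy <- function(L, I0) log(I0 / pmax(rpois(n, I0 * exp(-L)), 1))
  L80 <- noisy(L_true[1], I0_80)
  L140 <- noisy(L_true[2], I0_140)
  sol <- solveRay(L80, L140, sys)
  expect_lt(cor(sol$t_al - 1, sol$t_pmma - 15), -0.5)
})

test_that("polynomial calibration agrees with the Newton solver over its range", {
  sys <- defaultBasisSystem()
  wedge <- makeStepWedge(sys)
  cal <- calibratePolynomial(wedge, 3)
  # fit property: training residual bound holds on the wedge itself
  pred <- predict(cal, wedge$L_low, wedge$L_high)
  expect_lte(max(abs(pred$t_al - wedge$t_al)), cal$max_residual_cm + 1e-12)
  # cross-solver agreement on off-grid noiseless data
  g <- expand.grid(t_al = seq(0.2, 3.8, length.out = 7),
                   t_pmma = seq(1, 29, length.out = 7))
  L <- forwardDual(g$t_al, g$t_pmma, sys)
  p <- predict(cal, L[, 1], L[, 2])
  expect_lt(max(abs(p$t_al - g$t_al)), 0.1)
  expect_lt(max(abs(p$t_pmma - g$t_pmma)), 0.1)
  # under-determined fits are refused
  expect_error(calibratePolynomial(wedge[1:5, ], 3), "order too high")
})
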