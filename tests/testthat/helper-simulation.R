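# shared simulation fixtures, built once per test run and cached

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# reduced-scale geometry for cheap tests (same fan coverage, coarser detector)
small_geom <- function() geometrySpec(detector_columns = 128,
                                      detector_pixel_mm = 2.8125)

# noiseless dual-energy scan pair of the default phantom, 180 views
de_scans_noiseless <- function() cached("de_noiseless", {
  spec <- defaultCatphan()
  g <- small_geom()
  list(
    p80 = acquire(spec, protocolFromMas(80, 1000, 3), g, noise = FALSE),
    p140 = acquire(spec, protocolFromMas(140, 500, 3), g, noise = FALSE),
    geom = g)
})

# basis sinogram + images from the noiseless pair
de_basis_noiseless <- function() cached("de_basis_noiseless", {
  sc <- de_scans_noiseless()
  bs <- decompose(sc$p80, sc$p140)
  grid <- reconGrid(128, 1.75)
  list(sino = bs, images = reconstructBasis(bs, sc$geom, grid, "hann"),
       grid = grid, geom = sc$geom)
})

# noisy dual-energy pair at full 128^2 / 180-view test scale (default geometry
# detector) used by the fast-vs-oracle equivalence checks
de_noisy_128 <- function() cached("de_noisy_128", {
  spec <- defaultCatphan()
  g <- geometrySpec()
  p80 <- acquire(spec, protocolFromMas(80, 2430, 3), g, seed = 11L)
  p140 <- acquire(spec, protocolFromMas(140, 488, 3), g, seed = 12L)
  bs <- decompose(p80, p140)
  grid <- reconGrid(128, 1.75)
  list(sino = bs, images = reconstructBasis(bs, g, grid, "hann"),
       grid = grid, geom = g)
})

grid_mask <- function(grid, cx, cy, r) {
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}
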