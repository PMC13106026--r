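#' Map an attenuation volume to Hounsfield units
#'
#' Energy-consistent HU: the water reference is evaluated at the same energy
#' as the image, so water is 0 HU and vacuum -1000 HU at every synthesized
#' energy.
#'
#' @param mu_values attenuation matrix (cm^-1).
#' @param energy keV.
#' @keywords internal
.hu_map <- function(mu_values, energy) {
  mu_w <- linearAttenuation("water", energy)
  1000 * (mu_values - mu_w) / mu_w
}

#' Fast virtual monoenergetic image synthesis
#'
#' Voxel-wise linear combination of the two reconstructed basis images:
#' `mu(x) = mu_Al(E) w_al(x) + mu_PMMA(E) w_pmma(x)`, followed by HU mapping.
#' Because filtered backprojection is linear, this equals reconstructing the
#' energy-weighted sinogram directly ([synthesizeOracle()]) to floating-point
#' precision -- so a full energy sweep costs two reconstructions total.
#'
#' @param basis `basis_images` from [reconstructBasis()].
#' @param energy keV, within the energy grid.
#' @return object of class `vmi_volume` (a `volume` in HU plus `energy` and
#'   `method` fields).
#' @export
synthesizeFast <- function(basis, energy) {
  stopifnot(inherits(basis, "basis_images"))
  if (basis$w_al$unit != "basis_weight" || basis$w_pmma$unit != "basis_weight")
    stop("basis images must carry unit tag 'basis_weight'")
  mu <- linearAttenuation("aluminum", energy) * basis$w_al$values +
        linearAttenuation("pmma", energy) * basis$w_pmma$values
  v <- volume(.hu_map(mu, energy), basis$grid, unit = "hu",
              meta = list(energy = energy, method = "fast"))
  structure(c(v, list(energy = energy, method = "fast")), class = c("vmi_volume", "volume"))
}

#' Per-energy reconstruction oracle for VMI synthesis
#'
#' Reconstructs the single energy-weighted sinogram
#' `mu_Al(E) t_al + mu_PMMA(E) t_pmma` and HU-maps the result: the reference
#' path that reconstructs every energy from scratch.
#'
#' @param basis_sinogram a `basis_sinogram`.
#' @param geometry,grid,filter as in [reconstruct()].
#' @param energy keV.
#' @return a `vmi_volume`.
#' @export
synthesizeOracle <- function(basis_sinogram, geometry, grid, energy,
                             filter = "hann") {
  stopifnot(inherits(basis_sinogram, "basis_sinogram"))
  sino <- linearAttenuation("aluminum", energy) * basis_sinogram$t_al +
          linearAttenuation("pmma", energy) * basis_sinogram$t_pmma
  vol <- reconstruct(sino, geometry, grid, filter, basis_sinogram$angles,
                     unit = "mu")
  v <- volume(.hu_map(vol$values, energy), grid, unit = "hu",
              meta = list(energy = energy, method = "oracle"))
  structure(c(v, list(energy = energy, method = "oracle")),
            class = c("vmi_volume", "volume"))
}

#' Energy sweep of an image-quality metric
#'
#' Synthesizes VMIs over an energy range (default 40--150 keV in 1 keV steps)
#' by the fast path and evaluates the mean insert contrast-to-noise ratio
#' against the background ROI at each energy.  The metric is the mean of
#' absolute CNR over the insert ROIs, so bright and dark inserts both count
#' toward contrast.
#'
#' @param basis `basis_images`.
#' @param roiset an `roi_set` (needs `insert` and `background` roles).
#' @param e_min,e_max,step sweep range in keV.
#' @return object of class `energy_sweep`: `energies`, `metric`, `argmax_keV`.
#' @export
sweepEnergies <- function(basis, roiset, e_min = 40, e_max = 150, step = 1) {
  ins <- roiset[roiset$role == "insert", , drop = FALSE]
  bkg <- roiset[roiset$role == "background", , drop = FALSE]
  if (nrow(ins) == 0 || nrow(bkg) == 0) stop("ROI set lacks insert or background ROIs")
  energies <- seq(e_min, e_max, by = step)
  grid <- basis$grid
  masks <- lapply(seq_len(nrow(ins)), function(i) .roi_mask(grid, ins[i, ]))
  bmask <- .roi_mask(grid, bkg[1, ])
  metric <- vapply(energies, function(E) {
    v <- synthesizeFast(basis, E)
    bs <- .mask_stats(v$values, bmask)
    mean(vapply(masks, function(m) {
      s <- .mask_stats(v$values, m)
      abs(cnr(s, bs))
    }, numeric(1)))
  }, numeric(1))
  if (all(is.na(metric))) stop("metric is NaN at every energy")
  structure(list(energies = energies, metric = metric,
                 argmax_keV = energies[which.max(metric)]),
            class = "energy_sweep")
}

#' CNR-optimal energy of a sweep
#'
#' Energy at which the sweep metric is maximal; exact ties break toward the
#' lowest energy (`which.max` convention on an ascending grid).
#'
#' @param sweep an `energy_sweep`.
#' @return keV.
#' @export
optimalEnergy <- function(sweep) {
  stopifnot(inherits(sweep, "energy_sweep"), length(sweep$energies) > 0)
  if (all(is.na(sweep$metric))) stop("all-NaN sweep metric")
  sweep$energies[which.max(sweep$metric)]
}

#' @export
print.energy_sweep <- function(x, ...) {
  cat(sprintf("<energy sweep>  %g-%g keV (%d points), optimum %g keV (metric %.3g)\n",
              min(x$energies), max(x$energies), length(x$energies),
              x$argmax_keV, max(x$metric)))
  invisible(x)
}

#' Gaussian denoising of a VMI
#'
#' Optional isotropic Gaussian smoothing (sigma in voxels, separable truncated
#' kernel); `sigma = 0` is the identity.  Off by default throughout the
#' pipeline.
#'
#' @param vmi a `vmi_volume` (or plain `volume`).
#' @param sigma standard deviation in voxels, >= 0.
#' @return same class as input.
#' @export
denoise <- function(vmi, sigma = 0) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vmi)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm <- function(m) {
    # replicate-pad rows then columns, 1D convolutions
    pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
    one <- function(v) as.vector(stats::filter(pad(v), k, sides = 2))[(r + 1):(r + length(v))]
    m <- apply(m, 2, one)
    t(apply(t(m), 2, one))
  }
  vmi$values <- sm(vmi$values)
  vmi
}
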