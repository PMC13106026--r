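#' Reconstruction grid
#'
#' Square in-plane grid centered on the rotation axis; pixel centers at
#' `(i - (n-1)/2) * voxel_mm`, 0-based row-major with y increasing downward.
#'
#' @param n grid dimension (pixels per side).
#' @param voxel_mm pixel size in mm.
#' @return object of class `recon_grid` with precomputed center coordinates
#'   `x` (columns) and `y` (rows) in mm.
#' @export
reconGrid <- function(n = 128, voxel_mm = 1.75) {
  stopifnot(n > 0, voxel_mm > 0)
  idx <- seq_len(n) - 1
  coord <- (idx - (n - 1) / 2) * voxel_mm
  structure(list(n = as.integer(n), voxel_mm = voxel_mm, x = coord, y = coord),
            class = "recon_grid")
}

#' Volume (reconstructed image) container
#' @param values numeric matrix (n x n).
#' @param grid the `recon_grid`.
#' @param unit one of `"mu"` (cm^-1), `"basis_weight"`, `"hu"`.
#' @param meta optional metadata list (energy, provenance, ...).
#' @return object of class `volume`.
#' @export
volume <- function(values, grid, unit = c("mu", "basis_weight", "hu"),
                   meta = list()) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), nrow(values) == grid$n, ncol(values) == grid$n,
            all(is.finite(values)))
  structure(list(values = values, grid = grid, unit = unit, meta = meta),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume %dx%d @ %g mm>  unit '%s', range [%.4g, %.4g]\n",
              x$grid$n, x$grid$n, x$grid$voxel_mm, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Number of filtered-backprojection calls performed so far
#'
#' Instrumentation counter used to verify that the fast VMI path performs
#' exactly two reconstructions however many energies are synthesized.
#' @param reset reset the counter to zero?
#' @return integer count (before any reset).
#' @export
reconCount <- function(reset = FALSE) {
  n <- if (is.null(.decbct$recon_calls)) 0L else .decbct$recon_calls
  if (reset) .decbct$recon_calls <- 0L
  n
}

# discrete ramp-filter frequency response on a padded FFT grid, built from the
# exact band-limited spatial kernel (h0 = 1/(4 du^2), odd taps -1/(pi n du)^2)
# so the DC level of reconstructed values is correct
.ramp_response <- function(m, du, filter) {
  h <- numeric(m)
  h[1] <- 1 / (4 * du^2)
  n_half <- m / 2
  n <- seq_len(n_half)
  odd <- n[n %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd * du)^2
  h[m + 1 - odd] <- -1 / (pi * odd * du)^2
  H <- Re(fft(h))
  if (filter == "hann") {
    f <- c(0:(m / 2), -(m / 2 - 1):-1) / (m * du)
    fnyq <- 1 / (2 * du)
    H <- H * 0.5 * (1 + cos(pi * abs(f) / fnyq))
  }
  H
}

# redundancy weights for an offset (half-fan) detector: smooth ramp over the
# doubly-sampled central band, so each ray pair sums to unit weight
.halffan_weights <- function(u, sad) {
  gam <- atan(u / sad)
  ov <- min(abs(min(gam)), abs(max(gam)))   # half-angle of the overlap band
  w <- rep(1, length(u))
  if (ov > 0) {
    inb <- abs(gam) < ov
    s <- sign(sum(gam))                     # side with the longer arm keeps 1
    w[inb] <- 0.5 * (1 + sin(pi * gam[inb] / (2 * ov)) * s)
    w[gam * s <= -ov] <- 0
  }
  2 * w
}

#' Fan-beam filtered backprojection
#'
#' Standard equidistant (flat-detector) fan-beam FBP over a full 360 degree
#' circular trajectory: cosine pre-weighting, ramp (optionally Hann-apodized)
#' filtering via FFT with the exact discrete kernel, and distance-weighted
#' backprojection with linear interpolation.  The operator is linear in the
#' sinogram -- the property that makes fast VMI synthesis exact.
#'
#' @param sinogram numeric matrix, views x detector elements.
#' @param geometry a `geometry_spec`.
#' @param grid a `recon_grid`.
#' @param filter `"ramp"` or `"hann"`.
#' @param angles view angles in degrees (default: uniform 360 coverage).
#' @param unit unit tag for the output [volume()]; default `"mu"` with the
#'   sinogram interpreted as dimensionless line integrals, giving cm^-1.
#' @return a `volume`.
#' @export
reconstruct <- function(sinogram, geometry, grid, filter = c("hann", "ramp"),
                        angles = NULL, unit = "mu") {
  filter <- match.arg(filter)
  stopifnot(is.matrix(sinogram))
  if (ncol(sinogram) != geometry$detector_columns)
    stop("sinogram width does not match geometry detector_columns")
  if (is.null(angles))
    angles <- (seq_len(nrow(sinogram)) - 1) * 360 / nrow(sinogram)
  if (length(angles) != nrow(sinogram))
    stop("angle count does not match sinogram rows")
  arc <- diff(range(angles)) + (angles[2] - angles[1])
  if (abs(arc - 360) > 1e-6)
    stop("only full 360 degree arcs are supported")
  .decbct$recon_calls <- reconCount() + 1L

  sad <- geometry$source_axis_mm
  u <- .detector_u_iso(geometry)
  du <- u[2] - u[1]
  nu <- length(u)
  # cosine pre-weight (flat detector rescaled to the isocenter line)
  wcos <- sad / sqrt(sad^2 + u^2)
  if (geometry$lateral_offset_mm != 0) wcos <- wcos * .halffan_weights(u, sad)
  p <- sweep(sinogram, 2, wcos, "*")
  # ramp filtering, rows are views
  m <- 2^ceiling(log2(2 * nu))
  H <- .ramp_response(m, du, filter)
  P <- matrix(0, m, nrow(p))
  P[seq_len(nu), ] <- t(p)
  Q <- Re(mvfft(mvfft(P) * H, inverse = TRUE)) / m
  q <- t(Q[seq_len(nu), , drop = FALSE]) * du

  n <- grid$n
  X <- matrix(grid$x, n, n, byrow = TRUE)
  Y <- matrix(grid$y, n, n)
  f <- matrix(0, n, n)
  dbeta <- 2 * pi / length(angles)
  for (a in seq_along(angles)) {
    beta <- angles[a] * pi / 180
    L <- sad - (X * cos(beta) + Y * sin(beta))      # distance along central ray
    tt <- -X * sin(beta) + Y * cos(beta)
    uu <- sad * tt / L
    U2 <- (L / sad)^2
    pos <- (uu - u[1]) / du + 1
    i0 <- floor(pos)
    w1 <- pos - i0
    ok <- i0 >= 1 & i0 < nu
    row <- q[a, ]
    vals <- numeric(length(pos))
    vals[ok] <- row[i0[ok]] * (1 - w1[ok]) + row[i0[ok] + 1] * w1[ok]
    f <- f + vals / U2
  }
  f <- f * dbeta / 2
  # geometry is in mm; convert line-integral reconstructions to per-cm
  volume(f * 10, grid, unit = unit,
         meta = list(filter = filter, n_views = length(angles)))
}

#' Reconstruct both basis-material sinograms
#'
#' Applies [reconstruct()] independently to the Al and PMMA
#' equivalent-thickness sinograms (cm); because the thickness sinograms are in
#' cm, the reconstructed voxel values are dimensionless local volume fractions
#' of each basis material.
#'
#' @param basis a `basis_sinogram` from [decompose()].
#' @param geometry,grid,filter as in [reconstruct()].
#' @return object of class `basis_images`: volumes `w_al`, `w_pmma`.
#' @export
reconstructBasis <- function(basis, geometry, grid, filter = "hann") {
  stopifnot(inherits(basis, "basis_sinogram"))
  # thickness sinograms are in cm, so the per-cm output scale of
  # reconstruct() directly yields dimensionless volume fractions
  w_al <- reconstruct(basis$t_al, geometry, grid, filter, basis$angles,
                      unit = "basis_weight")
  w_pmma <- reconstruct(basis$t_pmma, geometry, grid, filter, basis$angles,
                        unit = "basis_weight")
  structure(list(w_al = w_al, w_pmma = w_pmma, grid = grid),
            class = "basis_images")
}

#' @export
print.basis_images <- function(x, ...) {
  cat(sprintf("<basis images %dx%d>  w_al range [%.3g, %.3g], w_pmma range [%.3g, %.3g]\n",
              x$grid$n, x$grid$n, min(x$w_al$values), max(x$w_al$values),
              min(x$w_pmma$values), max(x$w_pmma$values)))
  invisible(x)
}

#' Write a volume as NIfTI with a JSON sidecar
#' @param vol a `volume`; @param path output path without extension.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, pixdim = rep(vol$grid$voxel_mm, 2))
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  side <- c(list(unit = vol$unit, n = vol$grid$n, voxel_mm = vol$grid$voxel_mm),
            vol$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
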