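#' CBCT acquisition protocol
#'
#' A pulsed acquisition: tube potential, tube current, pulse width and
#' framerate over a fixed-duration gantry rotation.  Cumulative mAs is
#' `ma * pulse_ms/1000 * pulse_count`.
#'
#' @param kvp tube potential, kV.
#' @param ma tube current, mA.
#' @param pulse_ms pulse width, ms.
#' @param framerate pulses per second.
#' @param rotation_s rotation duration in s (default 60).
#' @param arc_deg gantry arc in degrees, in (0, 360].
#' @return object of class `protocol_spec`.
#' @export
protocolSpec <- function(kvp, ma, pulse_ms, framerate, rotation_s = 60,
                         arc_deg = 360) {
  vals <- c(kvp = kvp, ma = ma, pulse_ms = pulse_ms, framerate = framerate,
            rotation_s = rotation_s, arc_deg = arc_deg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all protocol fields must be positive and finite")
  if (arc_deg > 360) stop("arc_deg must lie in (0, 360]")
  structure(as.list(vals), class = "protocol_spec")
}

#' Protocol with a prescribed cumulative mAs
#'
#' Convenience constructor used for the dual-energy run matrix, where runs are
#' specified by total mAs and framerate: the tube current is back-computed so
#' that `cumulativeMas()` reproduces the requested total.
#'
#' @param kvp kV; @param cumulative_mas total mAs over the scan.
#' @param framerate pulses per second; @param pulse_ms pulse width (default 20).
#' @inheritParams protocolSpec
#' @export
protocolFromMas <- function(kvp, cumulative_mas, framerate, pulse_ms = 20,
                            rotation_s = 60, arc_deg = 360) {
  n <- round(framerate * rotation_s * arc_deg / 360)
  ma <- cumulative_mas / (n * pulse_ms / 1000)
  protocolSpec(kvp, ma, pulse_ms, framerate, rotation_s, arc_deg)
}

#' Number of pulses (projection views) in a protocol
#'
#' `round(framerate * rotation_s * arc_deg/360)`; with the 60 s rotation this
#' reconciles mA, pulse width and framerate with the cumulative mAs printed
#' for standard protocol tables.
#' @param protocol a `protocol_spec`.
#' @export
pulseCount <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  round(protocol$framerate * protocol$rotation_s * protocol$arc_deg / 360)
}

#' Cumulative mAs of a protocol
#' @param protocol a `protocol_spec`.
#' @export
cumulativeMas <- function(protocol) {
  pulseCount(protocol) * protocol$ma * protocol$pulse_ms / 1000
}

#' mAs per pulse
#' @param protocol a `protocol_spec`.
#' @export
masPerPulse <- function(protocol) protocol$ma * protocol$pulse_ms / 1000

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol %g kVp>  %g mA x %g ms @ %g /s, %g s, %g deg -> %d pulses, %.1f mAs\n",
              x$kvp, x$ma, x$pulse_ms, x$framerate, x$rotation_s, x$arc_deg,
              pulseCount(x), cumulativeMas(x)))
  invisible(x)
}

#' Scanner geometry
#'
#' Fan-beam (2D, single detector row) or cone-beam (3D) circular geometry.
#' The default is a centered full-fan 2D geometry sized to cover a 20 cm
#' phantom with margin.  `lateral_offset_mm` shifts the detector laterally
#' (half-fan acquisition); redundancy weighting is then applied at
#' reconstruction.
#'
#' @param source_axis_mm source-to-rotation-axis distance (SAD).
#' @param source_detector_mm source-to-detector distance (SDD).
#' @param detector_pixel_mm detector element pitch at the detector plane.
#' @param detector_columns number of detector elements per row.
#' @param detector_rows rows (1 for fan mode).
#' @param lateral_offset_mm detector lateral shift at the detector plane.
#' @param mode `"fan2d"` or `"cone3d"` (only `"fan2d"` is implemented).
#' @return object of class `geometry_spec`.
#' @export
geometrySpec <- function(source_axis_mm = 1000, source_detector_mm = 1500,
                         detector_pixel_mm = 1.4, detector_columns = 256,
                         detector_rows = 1, lateral_offset_mm = 0,
                         mode = c("fan2d", "cone3d")) {
  mode <- match.arg(mode)
  if (mode != "fan2d") stop("only fan2d geometry is implemented")
  if (!(source_detector_mm > source_axis_mm) || source_axis_mm <= 0)
    stop("require source_detector > source_axis > 0")
  if (detector_columns <= 0) stop("detector_columns must be positive")
  structure(list(source_axis_mm = source_axis_mm,
                 source_detector_mm = source_detector_mm,
                 detector_pixel_mm = detector_pixel_mm,
                 detector_columns = as.integer(detector_columns),
                 detector_rows = as.integer(detector_rows),
                 lateral_offset_mm = lateral_offset_mm, mode = mode),
            class = "geometry_spec")
}

# detector element coordinates rescaled onto the line through the isocenter
# perpendicular to the central ray (virtual detector at the axis)
.detector_u_iso <- function(geometry) {
  mag <- geometry$source_axis_mm / geometry$source_detector_mm
  du <- geometry$detector_pixel_mm * mag
  k <- seq_len(geometry$detector_columns) - 1
  (k - (geometry$detector_columns - 1) / 2) * du + geometry$lateral_offset_mm * mag
}

#' Analytic ray tracing through a phantom
#'
#' Intersection lengths (cm) of every detector-element ray with each material
#' region of the phantom, for one source angle.  Regions are circles, so
#' chords are computed in closed form; the background length is the outer
#' chord minus the insert chords.
#'
#' @param spec a `phantom_spec`.
#' @param geometry a `geometry_spec`.
#' @param angle source angle in degrees.
#' @return matrix `detector_columns x n_materials` of path lengths in cm, with
#'   material names as column names.
#' @export
raytrace <- function(spec, geometry, angle) {
  beta <- angle * pi / 180
  sad <- geometry$source_axis_mm
  S <- sad * c(cos(beta), sin(beta))
  tv <- c(-sin(beta), cos(beta))
  u <- .detector_u_iso(geometry)
  # unit ray directions from source to each virtual detector element
  dx <- u * tv[1] - S[1]
  dy <- u * tv[2] - S[2]
  nrm <- sqrt(dx^2 + dy^2)
  dx <- dx / nrm; dy <- dy / nrm

  chord <- function(cx, cy, r) {
    vx <- cx - S[1]; vy <- cy - S[2]
    proj <- vx * dx + vy * dy
    d2 <- (vx^2 + vy^2) - proj^2
    len <- 2 * sqrt(pmax(r^2 - d2, 0))
    len[proj <= 0] <- 0
    len / 10   # mm -> cm
  }

  mats <- unique(c(spec$background_material,
                   vapply(spec$inserts, function(i) i$material, character(1))))
  out <- matrix(0, length(u), length(mats), dimnames = list(NULL, mats))
  outer_chord <- chord(0, 0, spec$outer_radius)
  out[, spec$background_material] <- outer_chord
  for (ins in spec$inserts) {
    ic <- chord(ins$center[1], ins$center[2], ins$radius)
    out[, ins$material] <- out[, ins$material] + ic
    out[, spec$background_material] <- out[, spec$background_material] - ic
  }
  out
}

#' Expected detector signal for one pulse
#'
#' Polyenergetic Beer-Lambert transport:
#' `I = sum_E fluence(E) * mAs * fluence_scale * w(E) * exp(-sum_m mu_m(E) t_m)`
#' with `w(E) = E` for the energy-integrating detector; `I0` is the open-field
#' value (all path lengths zero).  `fluence_scale` sets the expected-photon
#' units used by the Poisson noise model.
#'
#' @param paths path-length matrix from [raytrace()] (cm, material columns).
#' @param spectrum a `spectrum`.
#' @param mAs_per_pulse mAs delivered in the pulse.
#' @param fluence_scale photons per element per mAs per unit relative fluence
#'   (default 40, chosen so the open-field reference-protocol pulse carries
#'   roughly 3e5 photon-equivalents per element).
#' @param response detector response, see [detectorWeights()].
#' @return list with vector `I` and scalar `I0`.
#' @export
simulatePulse <- function(paths, spectrum, mAs_per_pulse, fluence_scale = 40,
                          response = "ei") {
  .check_spectrum(spectrum)
  if (any(paths < 0)) stop("negative path length")
  w <- spectrum$fluence * detectorWeights(spectrum$energies, response)
  mu <- vapply(colnames(paths),
               function(m) linearAttenuation(m, spectrum$energies),
               numeric(length(spectrum$energies)))
  A <- paths %*% t(mu)                         # n_elem x n_E line integrals
  scale <- mAs_per_pulse * fluence_scale
  list(I = as.vector(exp(-A) %*% w) * scale, I0 = sum(w) * scale)
}

#' Poisson counting noise
#'
#' Independent Poisson draws with mean `I` (expected-photon units); the draw
#' is clamped away from zero so log line integrals stay finite.
#'
#' @param I expected signals (must satisfy `I <= I0`).
#' @param I0 open-field signal.
#' @param seed integer RNG seed; the same seed reproduces the draw exactly.
#' @return noisy signal vector.
#' @export
addNoise <- function(I, I0, seed) {
  if (any(I > I0 * (1 + 1e-12))) stop("I must not exceed I0")
  set.seed(seed)
  pmax(rpois(length(I), lambda = as.vector(I)), 0.5)
}

#' Expected (noiseless) sinogram
#'
#' Deterministic part of an acquisition: the expected detector signal at every
#' view angle for a unit pulse, reusable across noise realizations (the
#' expected signal is linear in mAs per pulse).
#'
#' @param spec phantom; @param geometry geometry; @param spectrum beam.
#' @param angles view angles in degrees.
#' @inheritParams simulatePulse
#' @return list: `I` (n_angles x n_elements), `I0` scalar, `angles`.
#' @export
expectedSinogram <- function(spec, geometry, spectrum, angles,
                             mAs_per_pulse = 1, fluence_scale = 40,
                             response = "ei") {
  .check_spectrum(spectrum)
  w <- spectrum$fluence * detectorWeights(spectrum$energies, response)
  mats <- unique(c(spec$background_material,
                   vapply(spec$inserts, function(i) i$material, character(1))))
  mu <- vapply(mats, function(m) linearAttenuation(m, spectrum$energies),
               numeric(length(spectrum$energies)))
  scale <- mAs_per_pulse * fluence_scale
  I <- matrix(0, length(angles), geometry$detector_columns)
  for (a in seq_along(angles)) {
    paths <- raytrace(spec, geometry, angles[a])
    A <- paths %*% t(mu[, colnames(paths), drop = FALSE])
    I[a, ] <- as.vector(exp(-A) %*% w) * scale
  }
  list(I = I, I0 = sum(w) * scale, angles = angles)
}

#' View angles of a protocol
#' @param protocol a `protocol_spec`.
#' @return degrees, uniformly spaced over the arc.
#' @export
protocolAngles <- function(protocol) {
  n <- pulseCount(protocol)
  if (n < 1) stop("protocol yields no pulses")
  (seq_len(n) - 1) * protocol$arc_deg / n
}

#' Projection set from a precomputed expected sinogram
#'
#' Applies Poisson noise (or not) and converts to log line integrals
#' `ln(I0/I)`.  Splitting acquisition this way lets several noise seeds reuse
#' one deterministic forward projection.
#'
#' @param expected output of [expectedSinogram()] computed at unit mAs.
#' @param protocol the `protocol_spec` (supplies kVp and mAs per pulse).
#' @param geometry the `geometry_spec`.
#' @param seed RNG seed (required when `noise = TRUE`).
#' @param noise add Poisson noise?
#' @return object of class `projection_set`.
#' @export
projectionSetFromExpected <- function(expected, protocol, geometry,
                                      seed = NULL, noise = TRUE) {
  mpp <- masPerPulse(protocol)
  I <- expected$I * mpp
  I0 <- expected$I0 * mpp
  if (noise) {
    if (is.null(seed)) stop("seed required for noisy acquisition")
    I <- matrix(addNoise(I, I0, seed), nrow(I), ncol(I))
  }
  structure(list(angles = expected$angles, line_integrals = log(I0 / I),
                 kvp = protocol$kvp, mAs_per_pulse = mpp,
                 seed = if (noise) seed else NA_integer_,
                 geometry = geometry, protocol = protocol),
            class = "projection_set")
}

#' Acquire a full CBCT scan
#'
#' Simulates the pulsed scan of a phantom under a protocol: uniform view
#' angles over the arc, polyenergetic forward projection, optional Poisson
#' noise, log conversion.
#'
#' @inheritParams projectionSetFromExpected
#' @param spec phantom.
#' @param spectrum beam; defaults to the package spectrum for the protocol kVp.
#' @inheritParams simulatePulse
#' @return a `projection_set` (fields: `angles`, `line_integrals`, `kvp`,
#'   `mAs_per_pulse`, `seed`).
#' @export
acquire <- function(spec, protocol, geometry = geometrySpec(), seed = NULL,
                    noise = TRUE, spectrum = NULL, fluence_scale = 40,
                    response = "ei") {
  if (is.null(spectrum)) spectrum <- defaultSpectrum(protocol$kvp)
  expected <- expectedSinogram(spec, geometry, spectrum, protocolAngles(protocol),
                               mAs_per_pulse = 1, fluence_scale = fluence_scale,
                               response = response)
  projectionSetFromExpected(expected, protocol, geometry, seed, noise)
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection set %g kVp>  %d views x %d elements, %.3g mAs/pulse, seed %s\n",
              x$kvp, nrow(x$line_integrals), ncol(x$line_integrals),
              x$mAs_per_pulse, as.character(x$seed)))
  invisible(x)
}
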