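#' Standard 1-keV energy grid
#'
#' Energies used throughout the package for spectra and VMI synthesis:
#' an ascending integer grid in keV with exactly 1 keV spacing, covering at
#' least 20--150 keV.
#'
#' @param emin,emax grid limits in keV; `emin` must be <= 40 and `emax` >= 150.
#' @return integer vector of energies in keV.
#' @export
energyGrid <- function(emin = 20, emax = 150) {
  if (emin > 40 || emax < 150) stop("energy grid must cover at least [40, 150] keV")
  seq.int(as.integer(emin), as.integer(emax), by = 1L)
}

.elemental_table <- function() {
  if (is.null(.decbct$elements)) {
    df <- read.csv(.decbct_extdata("elemental_mass_attenuation.csv"),
                   stringsAsFactors = FALSE)
    .decbct$elements <- split(df[c("energy_keV", "mu_rho_cm2_g")], df$element)
  }
  .decbct$elements
}

.composition_table <- function() {
  if (is.null(.decbct$compositions)) {
    df <- read.csv(.decbct_extdata("materials.csv"), stringsAsFactors = FALSE)
    .decbct$compositions <- split(df, df$material)
  }
  .decbct$compositions
}

#' Names of all embedded materials
#' @return character vector of material identifiers.
#' @export
materialNames <- function() sort(names(.composition_table()))

#' Material record: density and mass-attenuation table
#'
#' Builds a material from the embedded elemental mass-attenuation tables by the
#' mass-weighted mixture rule evaluated at the tabulated node energies.
#'
#' @param name material identifier, one of [materialNames()].
#' @return object of class `material_record` with fields `name`,
#'   `density` (g/cm^3) and `table` (data.frame `energy_keV`, `mu_rho_cm2_g`).
#' @export
materialRecord <- function(name) {
  if (!is.null(.decbct$materials[[name]])) return(.decbct$materials[[name]])
  comp <- .composition_table()[[name]]
  if (is.null(comp)) stop("unknown material: ", name)
  elems <- .elemental_table()
  energies <- elems[[comp$element[1]]]$energy_keV
  mu_rho <- rep(0, length(energies))
  for (i in seq_len(nrow(comp))) {
    tab <- elems[[comp$element[i]]]
    stopifnot(identical(tab$energy_keV, energies))
    mu_rho <- mu_rho + comp$mass_fraction[i] * tab$mu_rho_cm2_g
  }
  rec <- structure(
    list(name = name, density = comp$density_g_cm3[1],
         table = data.frame(energy_keV = energies, mu_rho_cm2_g = mu_rho)),
    class = "material_record")
  stopifnot(all(diff(energies) > 0), all(mu_rho > 0))
  if (is.null(.decbct$materials)) .decbct$materials <- list()
  .decbct$materials[[name]] <- rec
  rec
}

#' @export
print.material_record <- function(x, ...) {
  cat(sprintf("<material '%s'>  density %.4g g/cm^3, %d table nodes (%g-%g keV)\n",
              x$name, x$density, nrow(x$table),
              min(x$table$energy_keV), max(x$table$energy_keV)))
  invisible(x)
}

# log-log interpolation of a (energy, value) table; exact at nodes
.loglog_interp <- function(table, energy) {
  e <- table$energy_keV
  v <- table$mu_rho_cm2_g
  if (any(energy < min(e) | energy > max(e)))
    stop("energy outside tabulated range [", min(e), ", ", max(e), "] keV")
  exp(approx(log(e), log(v), xout = log(energy), rule = 1)$y)
}

#' Mass attenuation coefficient (cm^2/g)
#'
#' Log-log interpolation of the embedded table, the standard convention for
#' photon cross-section data.
#'
#' @param material material name or `material_record`.
#' @param energy energies in keV (vectorized); must lie inside the table range.
#' @return numeric vector, cm^2/g.
#' @export
massAttenuation <- function(material, energy) {
  rec <- if (inherits(material, "material_record")) material else materialRecord(material)
  .loglog_interp(rec$table, energy)
}

#' Linear attenuation coefficient (cm^-1)
#'
#' `density * mu/rho` with log-log interpolated mass attenuation; exact at the
#' table nodes and continuous in energy.
#'
#' @inheritParams massAttenuation
#' @return numeric vector, cm^-1.
#' @export
linearAttenuation <- function(material, energy) {
  rec <- if (inherits(material, "material_record")) material else materialRecord(material)
  rec$density * massAttenuation(rec, energy)
}
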