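#' Generate a filtered polyenergetic x-ray spectrum
#'
#' Analytic bremsstrahlung model: the unfiltered photon fluence per 1 keV bin
#' follows the classical thick-target shape `(kvp/E - 1)`, which is then
#' hardened by an aluminum filter of the given thickness via Beer-Lambert
#' attenuation.  Fluence is relative (arbitrary normalization shared between
#' kVp settings; absolute photon numbers are set later by mAs and the detector
#' fluence scale).  Bins above the tube potential are zero.  The result is
#' deterministic and bitwise reproducible for fixed inputs.
#'
#' @param kvp tube potential in kV; supported range 50--150 (80 and 140 are
#'   the dual-energy defaults).
#' @param filtration_mm_al added aluminum filtration in mm (>= 0); default 4.
#' @param grid energy grid from [energyGrid()].
#' @return object of class `spectrum` with fields `kvp`, `energies` (keV),
#'   `fluence` (relative photons per bin) and `filtration_mm_al`.
#' @export
generateSpectrum <- function(kvp, filtration_mm_al = 4, grid = energyGrid()) {
  if (!is.numeric(kvp) || length(kvp) != 1 || kvp < 50 || kvp > 150)
    stop("unsupported kvp setting: ", kvp, " (supported range 50-150 kV)")
  if (filtration_mm_al < 0) stop("filtration must be >= 0")
  fl <- pmax(kvp / grid - 1, 0)
  mu_al <- linearAttenuation("aluminum", grid)      # cm^-1
  fl <- fl * exp(-mu_al * filtration_mm_al / 10)
  structure(list(kvp = kvp, energies = grid, fluence = fl,
                 filtration_mm_al = filtration_mm_al),
            class = "spectrum")
}

.check_spectrum <- function(sp) {
  stopifnot(inherits(sp, "spectrum"),
            all(sp$fluence >= 0),
            all(sp$fluence[sp$energies > sp$kvp] == 0))
  if (!any(sp$fluence > 0)) stop("degenerate spectrum: all-zero fluence")
  invisible(sp)
}

#' Fluence-weighted mean energy of a spectrum (keV)
#' @param spectrum a `spectrum` object.
#' @export
meanEnergy <- function(spectrum) {
  .check_spectrum(spectrum)
  sum(spectrum$energies * spectrum$fluence) / sum(spectrum$fluence)
}

#' Detector energy-response weights
#'
#' Flat-panel detectors are energy-integrating: each photon contributes in
#' proportion to its energy.  A photon-counting response (unit weight) is
#' selectable.
#'
#' @param energies keV vector.
#' @param response `"ei"` (energy-integrating, default) or `"pc"`
#'   (photon-counting).
#' @return numeric weight vector.
#' @export
detectorWeights <- function(energies, response = c("ei", "pc")) {
  response <- match.arg(response)
  if (response == "ei") as.numeric(energies) else rep(1, length(energies))
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %g kVp>  %g mm Al filtration, mean energy %.1f keV, %d bins\n",
              x$kvp, x$filtration_mm_al, meanEnergy(x), length(x$energies)))
  invisible(x)
}

#' Write a spectrum to CSV (columns `energy_keV`, `value`)
#' @param spectrum a `spectrum` object.
#' @param path output file.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  .check_spectrum(spectrum)
  df <- data.frame(energy_keV = spectrum$energies, value = spectrum$fluence)
  attrline <- sprintf("# kvp=%g filtration_mm_al=%g", spectrum$kvp,
                      spectrum$filtration_mm_al)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attrline, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV written by [writeSpectrumCsv()]
#' @param path CSV file.
#' @return a `spectrum` object.
#' @export
readSpectrumCsv <- function(path) {
  header <- readLines(path, n = 1)
  kv <- regmatches(header, gregexpr("[a-z_]+=[0-9.]+", header))[[1]]
  meta <- as.list(as.numeric(sub(".*=", "", kv)))
  names(meta) <- sub("=.*", "", kv)
  df <- read.csv(path, comment.char = "#")
  structure(list(kvp = meta$kvp, energies = df$energy_keV, fluence = df$value,
                 filtration_mm_al = meta$filtration_mm_al),
            class = "spectrum")
}

#' Default spectrum for a protocol kVp
#'
#' The two dual-energy acquisition settings (80 and 140 kVp) with the package
#' default 4 mm Al filtration; cached after first use.
#' @param kvp tube potential in kV.
#' @keywords internal
defaultSpectrum <- function(kvp) {
  key <- paste0("spectrum_", kvp)
  if (is.null(.decbct[[key]])) .decbct[[key]] <- generateSpectrum(kvp)
  .decbct[[key]]
}
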