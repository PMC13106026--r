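#' Effective (detector-weighted) mean energy of a spectrum
#'
#' Mean energy under the detector response weighting; used as the water
#' reference energy when HU-mapping a single-energy polyenergetic
#' reconstruction.
#'
#' @param spectrum a `spectrum`; @param response see [detectorWeights()].
#' @return keV.
#' @export
effectiveEnergy <- function(spectrum, response = "ei") {
  w <- spectrum$fluence * detectorWeights(spectrum$energies, response)
  sum(spectrum$energies * w) / sum(w)
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: which dual-energy run of the run
#' matrix to simulate, reconstruction scale, filter, VMI energy, sweep range
#' and the seeds of all stochastic stages (explicit; nothing reads system
#' entropy).
#'
#' @param run row of [deRunMatrix()] to simulate (2-9; run 1 is the reference
#'   and is always simulated alongside).
#' @param seed base integer seed; per-stage seeds are derived as documented in
#'   [runSeeds()].
#' @param grid_n,voxel_mm reconstruction grid.
#' @param geometry a `geometry_spec`.
#' @param filter reconstruction filter.
#' @param energy VMI energy for the metric report, keV.
#' @param sweep_range c(min, max) keV for the CNR-optimal search.
#' @param denoise_sigma Gaussian sigma in voxels (0 = off, the default).
#' @param fluence_scale photon scale, see [simulatePulse()].
#' @param noise simulate Poisson noise?
#' @param output_dir optional directory for artifacts.
#' @return object of class `run_config`.
#' @export
runConfig <- function(run = 2, seed = 1, grid_n = 128, voxel_mm = 1.75,
                      geometry = geometrySpec(), filter = "hann", energy = 60,
                      sweep_range = c(40, 150), denoise_sigma = 0,
                      fluence_scale = 40, noise = TRUE, output_dir = NULL) {
  stopifnot(run %in% 2:9, seed == as.integer(seed))
  structure(list(run = run, seed = as.integer(seed), grid_n = grid_n,
                 voxel_mm = voxel_mm, geometry = geometry, filter = filter,
                 energy = energy, sweep_range = sweep_range,
                 denoise_sigma = denoise_sigma, fluence_scale = fluence_scale,
                 noise = noise, output_dir = output_dir),
            class = "run_config")
}

#' Per-stage seeds derived from the base seed
#'
#' Distinct fixed offsets per stochastic stage keep the three Poisson streams
#' (80 kVp scan, 140 kVp scan, reference scan) independent while remaining
#' fully determined by one integer.
#'
#' @param seed base integer seed.
#' @return named integer vector.
#' @export
runSeeds <- function(seed) {
  c(scan_80 = seed, scan_140 = seed + 700000L, reference = seed + 1400000L)
}

# cheap deterministic content hash for provenance (no external digest dep)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate the reference single-energy clinical scan
#'
#' 140 kVp reference protocol (1688 mAs, 15 /s), reconstructed and HU-mapped
#' at the effective beam energy.
#'
#' @param config a `run_config`.
#' @param spec phantom (default sensitometry module).
#' @return HU `volume`.
#' @export
simulateReference <- function(config, spec = defaultCatphan()) {
  prot <- protocolFromMas(140, 1688, 15)
  grid <- reconGrid(config$grid_n, config$voxel_mm)
  ps <- acquire(spec, prot, config$geometry,
                seed = runSeeds(config$seed)[["reference"]],
                noise = config$noise, fluence_scale = config$fluence_scale)
  vol <- reconstruct(ps$line_integrals, config$geometry, grid, config$filter,
                     ps$angles)
  e_eff <- effectiveEnergy(defaultSpectrum(140))
  volume(.hu_map(vol$values, e_eff), grid, unit = "hu",
         meta = list(energy = e_eff, method = "single_energy_reference"))
}

#' Run the full dual-energy pipeline
#'
#' Simulates the paired 80/140 kVp scans of the selected run, decomposes them
#' into Al/PMMA thickness sinograms, reconstructs the basis images, sweeps the
#' VMI energies for the CNR optimum, synthesizes the report VMI, computes all
#' image-quality metrics against the simulated reference scan, and estimates
#' the run's combined imaging dose from the kerma regressions.
#'
#' @param config a `run_config`.
#' @return list of class `pipeline_result`: `report` (`metrics_report`),
#'   `dose` (`dose_estimate`), `sweep` (`energy_sweep`), `optimal_keV`,
#'   `vmi`, `reference`, `basis`, `provenance`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- defaultCatphan()
  rois <- defaultRois(spec)
  grid <- reconGrid(config$grid_n, config$voxel_mm)
  runrow <- deRunMatrix()[config$run, ]
  seeds <- runSeeds(config$seed)

  p80 <- acquire(spec, protocolFromMas(80, runrow$mas_80, runrow$framerate_s),
                 config$geometry, seed = seeds[["scan_80"]],
                 noise = config$noise, fluence_scale = config$fluence_scale)
  p140 <- acquire(spec, protocolFromMas(140, runrow$mas_140, runrow$framerate_s),
                  config$geometry, seed = seeds[["scan_140"]],
                  noise = config$noise, fluence_scale = config$fluence_scale)
  basis_sino <- decompose(p80, p140)
  basis <- reconstructBasis(basis_sino, config$geometry, grid, config$filter)
  sweep <- sweepEnergies(basis, rois, config$sweep_range[1], config$sweep_range[2])
  vmi <- synthesizeFast(basis, config$energy)
  if (config$denoise_sigma > 0) vmi <- denoise(vmi, config$denoise_sigma)
  reference <- simulateReference(config, spec)
  report <- buildReport(vmi, reference, rois)
  dose <- runDoseEstimate(runrow$mas_80, runrow$mas_140)
  prov <- list(config_hash = .config_hash(config),
               package_version = as.character(utils::packageVersion("decbct")),
               seeds = as.list(seeds), run = config$run)
  out <- structure(list(report = report, dose = dose, sweep = sweep,
                        optimal_keV = optimalEnergy(sweep), vmi = vmi,
                        reference = reference, basis = basis,
                        basis_sinogram = basis_sino, rois = rois,
                        provenance = prov),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) writePipelineResult(out, config$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline result: run %d>  optimal energy %g keV\n",
              x$provenance$run, x$optimal_keV))
  print(x$report)
  print(x$dose)
  invisible(x)
}

#' CNR-optimal energy over repeated noise realizations
#'
#' Repeats the dual-energy simulation of one run-matrix row for several noise
#' seeds and records the CNR-optimal VMI energy of each; the deterministic
#' forward projection is computed once and only the Poisson draws,
#' decomposition, basis reconstruction and sweep are repeated.  The summary
#' statistic is the median argmax energy across seeds.
#'
#' @param run run-matrix row (2-9).
#' @param seeds integer vector of base seeds.
#' @param grid_n,voxel_mm,geometry,filter,fluence_scale as in [runConfig()].
#' @param sweep_range keV range searched.
#' @return list: `per_seed` (keV per seed), `median_keV`.
#' @export
optimalEnergyStudy <- function(run = 2, seeds = 1:5, grid_n = 128,
                               voxel_mm = 1.75, geometry = geometrySpec(),
                               filter = "hann", fluence_scale = 40,
                               sweep_range = c(40, 150)) {
  spec <- defaultCatphan()
  rois <- defaultRois(spec)
  grid <- reconGrid(grid_n, voxel_mm)
  runrow <- deRunMatrix()[run, ]
  prot80 <- protocolFromMas(80, runrow$mas_80, runrow$framerate_s)
  prot140 <- protocolFromMas(140, runrow$mas_140, runrow$framerate_s)
  angles <- protocolAngles(prot80)
  exp80 <- expectedSinogram(spec, geometry, defaultSpectrum(80), angles,
                            fluence_scale = fluence_scale)
  exp140 <- expectedSinogram(spec, geometry, defaultSpectrum(140), angles,
                             fluence_scale = fluence_scale)
  per_seed <- vapply(seeds, function(s) {
    sd <- runSeeds(s)
    p80 <- projectionSetFromExpected(exp80, prot80, geometry, sd[["scan_80"]])
    p140 <- projectionSetFromExpected(exp140, prot140, geometry, sd[["scan_140"]])
    basis <- reconstructBasis(decompose(p80, p140), geometry, grid, filter)
    sw <- sweepEnergies(basis, rois, sweep_range[1], sweep_range[2])
    optimalEnergy(sw)
  }, numeric(1))
  list(per_seed = per_seed, median_keV = median(per_seed))
}

#' Relative CNR of the 60 keV VMI over repeated noise realizations
#'
#' For each seed, simulates the dual-energy pair of the selected run and the
#' single-energy 140 kVp reference at the reference dose, synthesizes the VMI,
#' and computes the mean across inserts of the VMI-to-reference CNR ratios.
#' Deterministic forward projections are shared across seeds.  Because the
#' per-seed estimate pools noisy small-ROI noise estimates, the across-seed
#' mean is the stable summary.
#'
#' @inheritParams optimalEnergyStudy
#' @param energy VMI energy in keV.
#' @return list: `per_seed` mean rCNR values, `mean`.
#' @export
rcnrStudy <- function(run = 2, seeds = 1:5, energy = 60, grid_n = 128,
                      voxel_mm = 1.75, geometry = geometrySpec(),
                      filter = "hann", fluence_scale = 40) {
  spec <- defaultCatphan()
  rois <- defaultRois(spec)
  grid <- reconGrid(grid_n, voxel_mm)
  runrow <- deRunMatrix()[run, ]
  prot80 <- protocolFromMas(80, runrow$mas_80, runrow$framerate_s)
  prot140 <- protocolFromMas(140, runrow$mas_140, runrow$framerate_s)
  prot_ref <- protocolFromMas(140, 1688, 15)
  exp80 <- expectedSinogram(spec, geometry, defaultSpectrum(80),
                            protocolAngles(prot80), fluence_scale = fluence_scale)
  exp140 <- expectedSinogram(spec, geometry, defaultSpectrum(140),
                             protocolAngles(prot140), fluence_scale = fluence_scale)
  exp_ref <- if (identical(protocolAngles(prot_ref), protocolAngles(prot140)))
    exp140 else expectedSinogram(spec, geometry, defaultSpectrum(140),
                                 protocolAngles(prot_ref),
                                 fluence_scale = fluence_scale)
  e_eff <- effectiveEnergy(defaultSpectrum(140))
  per_seed <- vapply(seeds, function(s) {
    sd <- runSeeds(s)
    p80 <- projectionSetFromExpected(exp80, prot80, geometry, sd[["scan_80"]])
    p140 <- projectionSetFromExpected(exp140, prot140, geometry, sd[["scan_140"]])
    basis <- reconstructBasis(decompose(p80, p140), geometry, grid, filter)
    vmi <- synthesizeFast(basis, energy)
    pref <- projectionSetFromExpected(exp_ref, prot_ref, geometry,
                                      sd[["reference"]])
    rv <- reconstruct(pref$line_integrals, geometry, grid, filter, pref$angles)
    ref <- volume(1000 * (rv$values / linearAttenuation("water", e_eff) - 1),
                  grid, unit = "hu")
    rcnr(insertCnr(vmi, rois), insertCnr(ref, rois))$mean
  }, numeric(1))
  list(per_seed = per_seed, mean = mean(per_seed))
}

#' Serialize a metrics report (+ dose, provenance) to JSON
#' @param result a `pipeline_result`; @param path output file.
#' @export
reportToJson <- function(result, path) {
  rep <- result$report
  payload <- list(
    provenance = result$provenance,
    energy_keV = rep$energy,
    optimal_energy_keV = result$optimal_keV,
    cnr_vmi = as.list(rep$cnr_vmi),
    cnr_reference = as.list(rep$cnr_reference),
    rcnr = list(per_insert = as.list(rep$rcnr_per_insert),
                mean = rep$rcnr_mean, sd = rep$rcnr_sd),
    hu_accuracy = list(per_insert = rep$hu_accuracy$per_insert,
                       mean = rep$hu_accuracy$mean, sd = rep$hu_accuracy$sd,
                       max_abs = rep$hu_accuracy$max_abs),
    uniformity = list(vmi = rep$uniformity_vmi,
                      reference = rep$uniformity_reference),
    dose = unclass(result$dose))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write all artifacts of a pipeline result
#' @param result a `pipeline_result`; @param dir output directory.
#' @export
writePipelineResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reportToJson(result, file.path(dir, "report.json"))
  writeRoiSetCsv(result$rois, file.path(dir, "rois.csv"))
  writeVolume(result$vmi, file.path(dir, "vmi"))
  writeVolume(result$reference, file.path(dir, "reference"))
  write.csv(data.frame(energy_keV = result$sweep$energies,
                       metric = result$sweep$metric),
            file.path(dir, "sweep.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a projection set as CSV plus JSON sidecar
#'
#' Plain-text container: the line-integral matrix as CSV (rows = views) and a
#' JSON sidecar with angles, kVp, mAs per pulse and seed.
#'
#' @param pset a `projection_set`; @param path base path (no extension).
#' @export
writeSinogramCsv <- function(pset, path) {
  write.csv(pset$line_integrals, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(angles = pset$angles, kvp = pset$kvp,
                            mAs_per_pulse = pset$mAs_per_pulse,
                            seed = pset$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSinogramCsv
#' @export
readSinogramCsv <- function(path) {
  li <- as.matrix(read.csv(paste0(path, ".csv")))
  dimnames(li) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(angles = meta$angles, line_integrals = li, kvp = meta$kvp,
                 mAs_per_pulse = meta$mAs_per_pulse, seed = meta$seed,
                 geometry = NULL, protocol = NULL),
            class = "projection_set")
}

#' Generate a deterministic fixture bundle
#'
#' Small plain-text fixtures for tests and demos: a noisy dual-energy
#' sinogram pair of the default phantom at reduced scale, the embedded
#' kerma-validation table, the default ROI set and the two default spectra.
#'
#' @param size `"tiny"` (90 views, 96 detector columns) or `"small"`
#'   (180 views, 192 columns).
#' @param seed base seed.
#' @param dir output directory.
#' @return invisible character vector of files written.
#' @export
makeFixtures <- function(size = c("tiny", "small"), seed = 1, dir = tempfile()) {
  size <- match.arg(size)
  dims <- if (size == "tiny") c(views = 90, cols = 96) else c(views = 180, cols = 192)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- geometrySpec(detector_columns = dims[["cols"]],
                       detector_pixel_mm = 360 / dims[["cols"]])
  spec <- defaultCatphan()
  fr <- dims[["views"]] / 60
  p80 <- acquire(spec, protocolFromMas(80, 1000, fr), geom, seed = seed)
  p140 <- acquire(spec, protocolFromMas(140, 500, fr), geom, seed = seed + 1L)
  writeSinogramCsv(p80, file.path(dir, "sino_080kvp"))
  writeSinogramCsv(p140, file.path(dir, "sino_140kvp"))
  write.csv(kairValidationTable(), file.path(dir, "kair_validation.csv"),
            row.names = FALSE)
  writeRoiSetCsv(defaultRois(spec), file.path(dir, "rois.csv"))
  writeSpectrumCsv(defaultSpectrum(80), file.path(dir, "spectrum_080kvp.csv"))
  writeSpectrumCsv(defaultSpectrum(140), file.path(dir, "spectrum_140kvp.csv"))
  invisible(list.files(dir, full.names = TRUE))
}
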