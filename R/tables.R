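#' Standard CBCT dose-measurement protocol set
#'
#' The eight pulsed-acquisition settings used for the dose calibration
#' measurements, spanning framerates 3--15 /s and cumulative 90--1688 mAs over
#' a 60 s, 360 degree rotation.  Protocol 8 at 140 kVp is the clinical
#' pelvis-large reference protocol.
#'
#' @return data.frame: `protocol`, `framerate_s`, `ma`, `pulse_ms`,
#'   `cumulative_mAs` (printed values).
#' @export
cbctProtocols <- function() {
  data.frame(
    protocol = 1:8,
    framerate_s = c(3, 7, 11, 15, 15, 15, 15, 15),
    ma = c(75, 75, 75, 10, 45, 45, 65, 75),
    pulse_ms = c(25, 25, 25, 10, 10, 20, 20, 25),
    cumulative_mAs = c(338, 788, 1238, 90, 405, 810, 1170, 1688))
}

#' Dual-energy run matrix
#'
#' Nine evaluation runs: the single-energy 140 kVp clinical reference (run 1)
#' and eight dual-energy 80/140 kVp protocols at graded dose levels and
#' framerates.
#'
#' @return data.frame: `run`, `mas_80`, `mas_140`, `framerate_s`.
#' @export
deRunMatrix <- function() {
  data.frame(
    run = 1:9,
    mas_80 = c(NA, 4046, 4092, 3250, 3253, 2433, 2442, 2440, 2430),
    mas_140 = c(1688, 833, 825, 653, 660, 504, 495, 483, 488),
    framerate_s = c(15, 15, 11, 15, 11, 15, 11, 7, 3))
}

#' Air-kerma validation measurements
#'
#' Estimated and measured free-in-air kerma (mGy) for seven protocols at 80
#' and 140 kVp, with the printed percent differences; the embedded copy of the
#' published calibration/validation table.
#'
#' @return data.frame, one row per protocol x kVp.
#' @export
kairValidationTable <- function() {
  read.csv(.decbct_extdata("kair_validation.csv"))
}
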