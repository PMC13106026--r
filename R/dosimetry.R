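#' Ordinary least-squares linear calibration model
#'
#' Fits `y = slope * x + intercept` and records the fitted x-range so that
#' later evaluations outside it can be flagged as extrapolations.
#'
#' @param points data.frame or list with numeric `x` and `y` (>= 2 points,
#'   non-degenerate x).
#' @return object of class `linear_model`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `x_range`.
#' @export
fitLinear <- function(points) {
  x <- points$x; y <- points$y
  if (length(x) < 2 || length(y) != length(x)) stop("need >= 2 (x, y) points")
  if (sd(x) == 0) stop("zero variance in x: cannot fit")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n_points = length(x), x_range = range(x)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear model>  y = %.5g x + %.5g  (R^2 = %.4f, n = %d, x in [%g, %g])\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' Ion-chamber calibration
#'
#' @param nk chamber calibration coefficient, Gy/C.
#' @param electrometer_factor dimensionless electrometer correction.
#' @param temperature chamber temperature, degrees C.
#' @param pressure ambient pressure, kPa.
#' @return object of class `chamber_calibration`.
#' @export
chamberCalibration <- function(nk, electrometer_factor = 1,
                               temperature = 22, pressure = 101.325) {
  stopifnot(nk > 0, pressure > 0)
  structure(list(nk = nk, electrometer_factor = electrometer_factor,
                 temperature = temperature, pressure = pressure),
            class = "chamber_calibration")
}

# temperature-pressure correction to reference conditions 22 C, 101.325 kPa
.ptp_correction <- function(temperature, pressure) {
  (273.15 + temperature) / (273.15 + 22) * 101.325 / pressure
}

#' Air kerma from integrated chamber charge
#'
#' `K_air = charge * N_k * electrometer_factor * P_TP`, reported in mGy.
#'
#' @param charge integrated charge in C (> 0).
#' @param cal a `chamber_calibration`.
#' @return mGy.
#' @export
kairFromCharge <- function(charge, cal) {
  if (any(charge <= 0)) stop("charge must be positive")
  gy <- charge * cal$nk * cal$electrometer_factor *
    .ptp_correction(cal$temperature, cal$pressure)
  gy * 1000
}

#' Evaluate a kerma-vs-mAs calibration at a cumulative mAs
#'
#' `slope * mAs + intercept`; the result is flagged when the mAs lies outside
#' the fitted range (linear calibrations are least trustworthy when
#' extrapolated toward very low mAs).
#'
#' @param model a `linear_model` of K_air (mGy) against cumulative mAs.
#' @param mAs cumulative mAs (>= 0).
#' @return list `kair_mGy`, `extrapolated`.
#' @export
estimateKair <- function(model, mAs) {
  if (any(mAs < 0)) stop("mAs must be non-negative")
  list(kair_mGy = model$slope * mAs + model$intercept,
       extrapolated = mAs < model$x_range[1] | mAs > model$x_range[2])
}

#' Combined dual-energy dose estimate
#'
#' Sum of the low- and high-energy air kermas and the relative dose as a
#' rounded integer percentage of the reference protocol kerma.
#'
#' @param est_low,est_high K_air of the two scans, mGy (>= 0).
#' @param reference reference-protocol K_air, mGy (> 0).
#' @param extrapolation_flag carried through from [estimateKair()].
#' @return object of class `dose_estimate`: `kair_80`, `kair_140`, `combined`,
#'   `relative_percent`, `extrapolation_flag`.
#' @export
combinedDose <- function(est_low, est_high, reference,
                         extrapolation_flag = FALSE) {
  stopifnot(est_low >= 0, est_high >= 0)
  if (reference <= 0) stop("reference dose must be positive")
  combined <- est_low + est_high
  structure(list(kair_80 = est_low, kair_140 = est_high, combined = combined,
                 relative_percent = round(100 * combined / reference),
                 extrapolation_flag = extrapolation_flag),
            class = "dose_estimate")
}

#' Signed percent difference between estimate and measurement
#'
#' `100 * (estimate - measurement) / measurement`, reported to one decimal.
#'
#' @param estimate,measurement mGy; measurement must be > 0.
#' @return percent, one decimal.
#' @export
percentDifference <- function(estimate, measurement) {
  if (any(measurement <= 0)) stop("measurement must be positive")
  round(100 * (estimate - measurement) / measurement, 1)
}

#' Weighted cone-beam dose index
#'
#' `CBDIw = (1/3) center + (2/3) mean(peripheral)` -- the standard weighted
#' dose-index convention for one central and four peripheral chamber
#' positions.
#'
#' @param center central measurement, mGy.
#' @param peripheral exactly four peripheral measurements, mGy.
#' @return mGy.
#' @export
cbdiw <- function(center, peripheral) {
  if (length(peripheral) != 4) stop("exactly 4 peripheral values required")
  center / 3 + 2 / 3 * mean(peripheral)
}

#' Convert a body-phantom dose index to the head-phantom scale
#'
#' Applies the published 2.34 conversion factor between the 32 cm body and
#' 16 cm head PMMA phantom dose indices so the two kVp datasets share a scale.
#'
#' @param cbdi_body mGy (>= 0).
#' @return mGy.
#' @export
convertPhantom <- function(cbdi_body) {
  stopifnot(all(cbdi_body >= 0))
  2.34 * cbdi_body
}

#' Correlate a dose index with air kerma across protocols
#'
#' Fits CBDI (or CBDIw) against K_air on protocol-paired records; the strength
#' of this regression is what licenses K_air as a surrogate dose metric.
#'
#' @param cbdi_records data.frame with `protocol` and `cbdi` columns.
#' @param kair_records data.frame with `protocol` and `kair` columns.
#' @return a `linear_model` of cbdi against kair.
#' @export
correlateSurrogate <- function(cbdi_records, kair_records) {
  if (!setequal(cbdi_records$protocol, kair_records$protocol) ||
      nrow(cbdi_records) != nrow(kair_records))
    stop("records are not paired by protocol")
  m <- merge(cbdi_records, kair_records, by = "protocol")
  fitLinear(list(x = m$kair, y = m$cbdi))
}

#' Kerma-vs-mAs calibration refit from the embedded validation table
#'
#' Ordinary least squares of measured K_air against cumulative mAs for one
#' tube potential, using the embedded seven-protocol measurement set.
#'
#' @param kvp 80 or 140.
#' @param use one of `"measured"` (default) or `"estimate"` -- which column to
#'   regress.
#' @return a `linear_model`.
#' @export
kairModel <- function(kvp, use = c("measured", "estimate")) {
  use <- match.arg(use)
  tab <- kairValidationTable()
  tab <- tab[tab$kvp == kvp, ]
  if (nrow(tab) == 0) stop("no validation data for kvp ", kvp)
  col <- if (use == "measured") "measured_mGy" else "estimate_mGy"
  fitLinear(list(x = tab$cumulative_mAs, y = tab[[col]]))
}

#' Dose summary for a dual-energy run
#'
#' Estimates the 80 and 140 kVp air kermas of a run from the mAs-regression
#' models and expresses their sum relative to the reference protocol
#' (1688 mAs at 140 kVp).
#'
#' @param mas_80,mas_140 cumulative mAs of the two scans.
#' @param model_80,model_140 `linear_model`s; default: refits of the embedded
#'   measured validation data.
#' @param reference_mas reference-protocol cumulative mAs at 140 kVp.
#' @return a `dose_estimate`.
#' @export
runDoseEstimate <- function(mas_80, mas_140,
                            model_80 = kairModel(80),
                            model_140 = kairModel(140),
                            reference_mas = 1688) {
  e80 <- estimateKair(model_80, mas_80)
  e140 <- estimateKair(model_140, mas_140)
  ref <- estimateKair(model_140, reference_mas)
  combinedDose(e80$kair_mGy, e140$kair_mGy, ref$kair_mGy,
               extrapolation_flag = e80$extrapolated || e140$extrapolated)
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose estimate>  80 kVp %.1f + 140 kVp %.1f = %.1f mGy (%d%% of reference)%s\n",
              x$kair_80, x$kair_140, x$combined, x$relative_percent,
              if (isTRUE(x$extrapolation_flag)) "  [extrapolated]" else ""))
  invisible(x)
}
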