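# pixel-center-in-disk membership mask for one ROI row
.roi_mask <- function(grid, roi) {
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  (X - roi$cx_mm)^2 + (Y - roi$cy_mm)^2 <= roi$r_mm^2
}

.mask_stats <- function(values, mask) {
  v <- values[mask]
  if (length(v) == 0) stop("empty ROI")
  # population standard deviation (divide by n)
  list(mean_hu = mean(v), sd_hu = sqrt(mean((v - mean(v))^2)),
       voxel_count = length(v))
}

#' ROI statistics on an HU volume
#'
#' Mean and population standard deviation over the voxels whose centers fall
#' inside the ROI disk.
#'
#' @param vol a `volume` with unit tag `"hu"`.
#' @param roi one row of an `roi_set` (fields `cx_mm`, `cy_mm`, `r_mm`).
#' @return list `mean_hu`, `sd_hu`, `voxel_count` (class `roi_stats`).
#' @export
roiStats <- function(vol, roi) {
  if (vol$unit != "hu") stop("roiStats expects an HU volume")
  out <- .mask_stats(vol$values, .roi_mask(vol$grid, roi))
  class(out) <- "roi_stats"
  out
}

#' Contrast-to-noise ratio between an insert and the background
#'
#' `CNR = (mean_i - mean_bkg) / sqrt((sd_i^2 + sd_bkg^2) / 2)`.
#'
#' @param insert,background `roi_stats` (or lists with `mean_hu`, `sd_hu`).
#' @return signed CNR (dimensionless).
#' @export
cnr <- function(insert, background) {
  den <- sqrt((insert$sd_hu^2 + background$sd_hu^2) / 2)
  if (den == 0) {
    if (insert$mean_hu == background$mean_hu) return(0)
    stop("degenerate ROIs: both standard deviations are zero")
  }
  (insert$mean_hu - background$mean_hu) / den
}

#' Relative CNR of a VMI against a reference image
#'
#' Elementwise ratio of per-insert CNR values; inserts whose reference CNR is
#' zero are excluded from the summary with a warning.
#'
#' @param cnr_vmi,cnr_reference named numeric vectors of per-insert CNR.
#' @return list: `per_insert` ratios, `mean`, `sd` (sample sd across inserts).
#' @export
rcnr <- function(cnr_vmi, cnr_reference) {
  stopifnot(length(cnr_vmi) == length(cnr_reference))
  keep <- cnr_reference != 0
  if (!all(keep))
    warning("excluding ", sum(!keep), " insert(s) with zero reference CNR")
  ratio <- cnr_vmi
  ratio[!keep] <- NA_real_
  ratio[keep] <- cnr_vmi[keep] / cnr_reference[keep]
  list(per_insert = ratio, mean = mean(ratio[keep]), sd = sd(ratio[keep]))
}

#' HU accuracy against theoretical insert values
#'
#' Per-insert deviation `delta_i = measured mean HU - theoreticalHu(material_i,
#' energy)` and the mean +/- sd across inserts.
#'
#' @param vol HU `volume`; @param roiset an `roi_set`; @param energy keV.
#' @return list: `per_insert` data.frame (`name`, `material`, `measured_hu`,
#'   `theoretical_hu`, `delta_hu`), `mean`, `sd`, `max_abs`.
#' @export
huAccuracy <- function(vol, roiset, energy) {
  ins <- roiset[roiset$role == "insert", , drop = FALSE]
  if (nrow(ins) == 0) stop("no insert ROIs")
  rows <- lapply(seq_len(nrow(ins)), function(i) {
    st <- roiStats(vol, ins[i, ])
    th <- theoreticalHu(ins$material[i], energy)
    data.frame(name = ins$name[i], material = ins$material[i],
               measured_hu = st$mean_hu, theoretical_hu = th,
               delta_hu = st$mean_hu - th, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_insert = per, mean = mean(per$delta_hu), sd = sd(per$delta_hu),
       max_abs = max(abs(per$delta_hu)))
}

#' HU uniformity
#'
#' Difference between the central ROI mean HU and the mean of the four
#' peripheral ROI means; a beam-hardening (cupping) indicator that vanishes on
#' a uniform image.
#'
#' @param vol HU `volume`.
#' @param roiset an `roi_set` containing exactly one `uniformity_center` and
#'   four `uniformity_peripheral` ROIs.
#' @return HU difference (center minus periphery).
#' @export
huUniformity <- function(vol, roiset) {
  cen <- roiset[roiset$role == "uniformity_center", , drop = FALSE]
  per <- roiset[roiset$role == "uniformity_peripheral", , drop = FALSE]
  if (nrow(cen) != 1 || nrow(per) != 4)
    stop("uniformity needs exactly 1 center and 4 peripheral ROIs")
  m_cen <- roiStats(vol, cen[1, ])$mean_hu
  m_per <- vapply(seq_len(4), function(i) roiStats(vol, per[i, ])$mean_hu,
                  numeric(1))
  m_cen - mean(m_per)
}

#' Per-insert CNR vector of a volume
#' @param vol HU `volume`; @param roiset an `roi_set`.
#' @return named numeric vector (one CNR per insert ROI).
#' @export
insertCnr <- function(vol, roiset) {
  ins <- roiset[roiset$role == "insert", , drop = FALSE]
  bkg <- roiset[roiset$role == "background", , drop = FALSE]
  if (nrow(bkg) == 0) stop("ROI set lacks a background ROI")
  bs <- roiStats(vol, bkg[1, ])
  out <- vapply(seq_len(nrow(ins)), function(i)
    cnr(roiStats(vol, ins[i, ]), bs), numeric(1))
  names(out) <- ins$name
  out
}

#' Assemble the full image-quality report
#'
#' Per-insert CNR and rCNR against a reference image, HU accuracy against the
#' theoretical insert values, and HU uniformity, with summary means and sds
#' recomputable from the per-insert values.
#'
#' @param vmi HU `vmi_volume` (or volume with `meta$energy`).
#' @param reference HU `volume` on the same grid (the clinical reference).
#' @param roiset an `roi_set`.
#' @param energy keV for theoretical HU; defaults to the VMI energy.
#' @return object of class `metrics_report`.
#' @export
buildReport <- function(vmi, reference, roiset, energy = NULL) {
  if (!isTRUE(all.equal(vmi$grid$n, reference$grid$n)))
    stop("VMI and reference grids differ")
  if (is.null(energy)) energy <- vmi$meta$energy %||% vmi$energy
  cnr_v <- insertCnr(vmi, roiset)
  cnr_r <- insertCnr(reference, roiset)
  rc <- rcnr(cnr_v, cnr_r)
  acc <- huAccuracy(vmi, roiset, energy)
  structure(list(energy = energy,
                 cnr_vmi = cnr_v, cnr_reference = cnr_r,
                 rcnr_per_insert = rc$per_insert,
                 rcnr_mean = rc$mean, rcnr_sd = rc$sd,
                 hu_accuracy = acc,
                 uniformity_vmi = huUniformity(vmi, roiset),
                 uniformity_reference = huUniformity(reference, roiset)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics report @ %g keV>\n", x$energy))
  cat(sprintf("  mean rCNR        %.2f +/- %.2f\n", x$rcnr_mean, x$rcnr_sd))
  cat(sprintf("  HU accuracy      %.1f +/- %.1f HU (max |dHU| %.1f)\n",
              x$hu_accuracy$mean, x$hu_accuracy$sd, x$hu_accuracy$max_abs))
  cat(sprintf("  HU uniformity    %.1f HU (reference %.1f HU)\n",
              x$uniformity_vmi, x$uniformity_reference))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
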