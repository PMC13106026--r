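#' Insert specification
#'
#' A circular material insert, positioned in-plane in mm with the origin at the
#' rotation axis (y increases downward in image display convention).
#'
#' @param name insert identifier.
#' @param center numeric length-2, (x, y) in mm.
#' @param radius radius in mm, > 0.
#' @param material material name resolvable by [materialRecord()].
#' @param module `"sensitometry"` or `"uniformity"`.
#' @return object of class `insert_spec`.
#' @export
insertSpec <- function(name, center, radius, material,
                       module = c("sensitometry", "uniformity")) {
  module <- match.arg(module)
  stopifnot(length(center) == 2, is.finite(center), radius > 0)
  materialRecord(material)   # resolve or fail
  structure(list(name = name, center = as.numeric(center), radius = radius,
                 material = material, module = module),
            class = "insert_spec")
}

#' Phantom specification (cylinder + inserts)
#'
#' @param outer_radius cylinder radius in mm.
#' @param background_material background material name.
#' @param inserts list of [insertSpec()] objects; must lie fully inside the
#'   cylinder and be pairwise non-overlapping.
#' @param name label.
#' @return object of class `phantom_spec`.
#' @export
phantomSpec <- function(outer_radius, background_material, inserts = list(),
                        name = "phantom") {
  stopifnot(outer_radius > 0)
  materialRecord(background_material)
  for (ins in inserts) {
    stopifnot(inherits(ins, "insert_spec"))
    if (sqrt(sum(ins$center^2)) + ins$radius > outer_radius)
      stop("insert '", ins$name, "' extends outside the phantom cylinder")
  }
  if (length(inserts) > 1) {
    for (i in seq_len(length(inserts) - 1)) for (j in (i + 1):length(inserts)) {
      d <- sqrt(sum((inserts[[i]]$center - inserts[[j]]$center)^2))
      if (d < inserts[[i]]$radius + inserts[[j]]$radius)
        stop("inserts '", inserts[[i]]$name, "' and '", inserts[[j]]$name,
             "' overlap")
    }
  }
  structure(list(name = name, outer_radius = outer_radius,
                 background_material = background_material, inserts = inserts),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom '%s'>  radius %g mm, background '%s', %d inserts\n",
              x$name, x$outer_radius, x$background_material, length(x$inserts)))
  invisible(x)
}

#' Default digital Catphan-style phantom
#'
#' A 20 cm diameter water-equivalent cylinder carrying a sensitometry ring of
#' nine 12 mm inserts (air, PMP, LDPE, polystyrene, acrylic, Delrin, Teflon and
#' two bone-mimicking inserts at 20% and 50% hydroxyapatite loading) centered
#' 55 mm from the axis at 40 degree spacing.  The uniformity module is the
#' same cylinder without inserts, obtained with `uniformity = TRUE`.
#'
#' @param uniformity if TRUE return the homogeneous uniformity module instead
#'   of the sensitometry module.
#' @return a `phantom_spec`.
#' @export
defaultCatphan <- function(uniformity = FALSE) {
  if (uniformity)
    return(phantomSpec(100, "water", name = "catphan_uniformity"))
  mats <- c("air", "pmp", "ldpe", "polystyrene", "acrylic",
            "delrin", "teflon", "bone20", "bone50")
  ring_r <- 55; ins_r <- 6
  inserts <- lapply(seq_along(mats), function(k) {
    th <- (k - 1) * 40 * pi / 180
    insertSpec(mats[k], ring_r * c(cos(th), sin(th)), ins_r, mats[k])
  })
  phantomSpec(100, "water", inserts, name = "catphan_sensitometry")
}

#' Default ROI layout for the phantom
#'
#' One disk ROI per sensitometry insert (radius 60% of the insert radius, to
#' keep clear of edge/partial-volume voxels), one background ROI on the insert
#' ring midway between the first two inserts, and the five uniformity ROIs:
#' one at the center plus four peripheral disks (top, bottom, left, right) at
#' 70% of the outer radius.
#'
#' @param spec a `phantom_spec` from [defaultCatphan()].
#' @param roi_frac insert ROI radius as a fraction of the insert radius.
#' @param uniformity_r_mm radius of the five uniformity ROIs in mm.
#' @return data.frame of class `roi_set` with columns `name`, `cx_mm`,
#'   `cy_mm`, `r_mm`, `role`, `material`.
#' @export
defaultRois <- function(spec = defaultCatphan(), roi_frac = 0.6,
                        uniformity_r_mm = 8) {
  rows <- lapply(spec$inserts, function(ins)
    data.frame(name = ins$name, cx_mm = ins$center[1], cy_mm = ins$center[2],
               r_mm = ins$radius * roi_frac, role = "insert",
               material = ins$material, stringsAsFactors = FALSE))
  ring_r <- if (length(spec$inserts)) sqrt(sum(spec$inserts[[1]]$center^2)) else 55
  r_roi <- if (length(spec$inserts)) spec$inserts[[1]]$radius * roi_frac else 4
  th <- 20 * pi / 180   # midway in the 40 degree gap between inserts 1 and 2
  rows <- c(rows, list(data.frame(
    name = "background", cx_mm = ring_r * cos(th), cy_mm = ring_r * sin(th),
    r_mm = r_roi, role = "background", material = spec$background_material,
    stringsAsFactors = FALSE)))
  peri <- 0.7 * spec$outer_radius
  upos <- rbind(center = c(0, 0), top = c(0, -peri), bottom = c(0, peri),
                left = c(-peri, 0), right = c(peri, 0))
  rows <- c(rows, lapply(rownames(upos), function(nm) data.frame(
    name = paste0("uniformity_", nm), cx_mm = upos[nm, 1], cy_mm = upos[nm, 2],
    r_mm = uniformity_r_mm,
    role = if (nm == "center") "uniformity_center" else "uniformity_peripheral",
    material = spec$background_material, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Write / read an ROI set as CSV
#' @param rois an `roi_set` data.frame.
#' @param path CSV file path.
#' @export
writeRoiSetCsv <- function(rois, path) {
  write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiSetCsv
#' @export
readRoiSetCsv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Rasterize a phantom onto a reconstruction grid
#'
#' Each pixel is labeled with the material whose shape contains its center
#' (inserts take precedence over background; outside the cylinder is air).
#'
#' @param spec a `phantom_spec`.
#' @param grid a `recon_grid` from [reconGrid()]; must cover the phantom.
#' @return character matrix (n x n) of material names.
#' @export
rasterize <- function(spec, grid) {
  ext <- max(abs(c(grid$x, grid$y))) + grid$voxel_mm / 2
  if (ext < spec$outer_radius)
    stop("reconstruction grid does not cover the phantom")
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)    # columns -> x
  Y <- matrix(grid$y, grid$n, grid$n)                  # rows -> y (downward)
  lab <- matrix("air", grid$n, grid$n)
  inside <- X^2 + Y^2 <= spec$outer_radius^2
  lab[inside] <- spec$background_material
  for (ins in spec$inserts) {
    m <- (X - ins$center[1])^2 + (Y - ins$center[2])^2 <= ins$radius^2
    lab[m] <- ins$material
  }
  lab
}

#' Theoretical Hounsfield units of a material at a given energy
#'
#' `1000 * (mu_m(E) - mu_w(E)) / mu_w(E)` using the embedded attenuation
#' tables; water is 0 HU at every energy by construction.
#'
#' @param material material name.
#' @param energy keV (vectorized).
#' @return HU value(s).
#' @export
theoreticalHu <- function(material, energy) {
  mu_m <- linearAttenuation(material, energy)
  mu_w <- linearAttenuation("water", energy)
  1000 * (mu_m - mu_w) / mu_w
}
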