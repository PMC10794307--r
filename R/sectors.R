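#' En-face vessel map
#'
#' Container for one OCTA en-face layer: a 2-D grid of vessel occupancy
#' values in \[0, 1\], its physical scale, the disc-center pixel (taken from
#' acquisition metadata, where the scan is manually centered on the disc),
#' the retinal layer and the eye. Grids are indexed \[row, col\] with row 1
#' at the top of the image (standard upright en-face orientation).
#'
#' @param grid numeric matrix with finite values in \[0, 1\].
#' @param mm_per_px pixel pitch in mm (isotropic).
#' @param center_px disc center as c(row, col); may be fractional.
#' @param layer `"RPC"` (radial peripapillary capillary), `"SVD"`
#'   (superficial) or `"DVD"` (deep).
#' @param laterality `"OD"` or `"OS"`.
#' @param source_id free-text identifier.
#' @return object of class `vessel_map`.
#' @export
vessel_map <- function(grid, mm_per_px, center_px = (dim(grid) + 1) / 2,
                       layer = c("RPC", "SVD", "DVD"),
                       laterality = c("OD", "OS"), source_id = "map") {
  layer <- match.arg(layer)
  laterality <- match.arg(laterality)
  grid <- as.matrix(grid)
  if (!all(is.finite(grid))) stop("map '", source_id, "': non-finite values")
  if (min(grid) < 0 || max(grid) > 1)
    stop("map '", source_id, "': values must lie in [0, 1]")
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("map '", source_id, "': mm_per_px must be positive")
  structure(list(grid = grid, mm_per_px = mm_per_px,
                 center_px = unname(center_px), layer = layer,
                 laterality = laterality, source_id = source_id),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map '%s'> %s %s, %dx%d px @ %.4f mm/px\n",
              x$source_id, x$layer, x$laterality,
              nrow(x$grid), ncol(x$grid), x$mm_per_px))
  invisible(x)
}

#' Parapapillary annulus mask
#'
#' Boolean mask of the measurement band: pixels whose centers lie at radial
#' distance in \[0.5, 1.5) mm from the disc center — the 3-mm-diameter ETDRS
#' band with the central 1-mm circle excluded.
#'
#' @param shape c(nrow, ncol) of the grid.
#' @param center_px disc center c(row, col).
#' @param mm_per_px pixel pitch in mm.
#' @param inner_mm,outer_mm annulus radii in mm (defaults: 1-3 mm diameters).
#' @return logical matrix of the given shape.
#' @export
annulus_mask <- function(shape, center_px, mm_per_px,
                         inner_mm = 0.5, outer_mm = 1.5) {
  stopifnot(inner_mm < outer_mm, mm_per_px > 0)
  margin <- outer_mm / mm_per_px
  if (center_px[1] - margin < 1 || center_px[1] + margin > shape[1] ||
      center_px[2] - margin < 1 || center_px[2] + margin > shape[2])
    stop(sprintf(
      "annulus (outer radius %.2f mm = %.1f px) exceeds grid bounds: center (%.1f, %.1f) needs a %.1f px margin in a %d x %d grid",
      outer_mm, margin, center_px[1], center_px[2], margin,
      shape[1], shape[2]))
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center_px[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) -
    center_px[2]
  d <- sqrt(r^2 + cc^2) * mm_per_px
  d >= inner_mm & d < outer_mm
}

#' Quadrant sector masks
#'
#' Splits the annulus into four 90-degree sectors by the +/-45-degree
#' diagonals through the disc center (ETDRS convention), centered on the
#' image vertical and horizontal meridians. Angles are measured
#' counter-clockwise from image-right with +y superior (image up); sectors
#' are half-open: superior = \[45, 135), inferior = \[225, 315), and the two
#' horizontal sectors are labeled nasal/temporal by laterality — in upright
#' en-face orientation the temporal side is image-left of center for OD and
#' image-right for OS.
#'
#' @inheritParams annulus_mask
#' @param laterality `"OD"` or `"OS"`.
#' @return named list of logical matrices `superior`, `inferior`, `nasal`,
#'   `temporal`; disjoint, union equal to the annulus.
#' @export
quadrant_masks <- function(shape, center_px, mm_per_px,
                           laterality = c("OD", "OS"),
                           inner_mm = 0.5, outer_mm = 1.5) {
  laterality <- match.arg(laterality)
  ann <- annulus_mask(shape, center_px, mm_per_px, inner_mm, outer_mm)
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center_px[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) -
    center_px[2]
  # +y superior: image row increases downward, so y = -r
  ang <- atan2(-r, cc) * 180 / pi
  ang <- (ang + 360) %% 360
  sup <- ann & ang >= 45 & ang < 135
  inf <- ann & ang >= 225 & ang < 315
  left <- ann & ang >= 135 & ang < 225
  right <- ann & (ang >= 315 | ang < 45)
  if (laterality == "OD") {
    list(superior = sup, inferior = inf, nasal = right, temporal = left)
  } else {
    list(superior = sup, inferior = inf, nasal = left, temporal = right)
  }
}

# Binarize a vessel grid: values already in {0,1} pass through, anything
# else is thresholded at >= 0.5 (device maps report area fraction of a
# binarized slab).
binarize_grid <- function(grid, threshold = 0.5) {
  u <- unique(as.vector(grid))
  if (all(u %in% c(0, 1))) return(grid)
  (grid >= threshold) * 1
}

#' Vessel density within a mask
#'
#' Percentage of mask pixels occupied by vessels after binarization.
#'
#' @param map a [vessel_map].
#' @param mask logical matrix of the same shape.
#' @param threshold binarization threshold on \[0, 1\] grids.
#' @return density in percent \[0, 100\].
#' @export
vessel_density <- function(map, mask, threshold = 0.5) {
  stopifnot(inherits(map, "vessel_map"))
  if (!any(mask)) stop("empty mask: no pixels to measure")
  bin <- binarize_grid(map$grid, threshold)
  100 * sum(bin[mask]) / sum(mask)
}

#' Quadrant sector densities
#'
#' Vessel density in the superior, inferior, nasal and temporal sectors of
#' the parapapillary annulus, plus the annulus-wide density. The
#' area-weighted mean of the four sector densities equals the overall
#' density exactly (same pixels, partitioned).
#'
#' @param map a [vessel_map].
#' @inheritParams annulus_mask
#' @param threshold binarization threshold.
#' @param center_px optional override of the map's disc center (e.g. from
#'   contour morphometry).
#' @return object of class `sector_densities`: list with `superior`,
#'   `inferior`, `nasal`, `temporal`, `overall` (percent), `areas_px`,
#'   `layer`, `laterality`, `source_id`.
#' @export
sector_densities <- function(map, inner_mm = 0.5, outer_mm = 1.5,
                             threshold = 0.5, center_px = NULL) {
  stopifnot(inherits(map, "vessel_map"))
  ctr <- if (is.null(center_px)) map$center_px else center_px
  qs <- quadrant_masks(dim(map$grid), ctr, map$mm_per_px, map$laterality,
                       inner_mm, outer_mm)
  bin <- binarize_grid(map$grid, threshold)
  dens <- vapply(qs, function(m) 100 * sum(bin[m]) / sum(m), numeric(1))
  areas <- vapply(qs, sum, numeric(1))
  overall <- sum(dens * areas) / sum(areas)
  structure(list(superior = unname(dens["superior"]),
                 inferior = unname(dens["inferior"]),
                 nasal = unname(dens["nasal"]),
                 temporal = unname(dens["temporal"]),
                 overall = overall, areas_px = areas,
                 layer = map$layer, laterality = map$laterality,
                 source_id = map$source_id),
            class = "sector_densities")
}

#' @export
print.sector_densities <- function(x, ...) {
  cat(sprintf(
    "<sector_densities '%s'> %s %s\n  S %.2f%%  I %.2f%%  N %.2f%%  T %.2f%%  (overall %.2f%%)\n",
    x$source_id, x$layer, x$laterality,
    x$superior, x$inferior, x$nasal, x$temporal, x$overall))
  invisible(x)
}

#' @rdname sector_densities
#' @param x a `sector_densities`.
#' @param ... unused.
#' @export
as.data.frame.sector_densities <- function(x, ...) {
  data.frame(source_id = x$source_id, layer = x$layer,
             laterality = x$laterality, S = x$superior, I = x$inferior,
             N = x$nasal, T = x$temporal, overall = x$overall,
             stringsAsFactors = FALSE)
}
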