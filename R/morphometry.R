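#' Longest disc diameter (longest chord)
#'
#' Finds the pair of contour vertices at maximal Euclidean distance: the
#' longest diameter (LD) of the optic disc. Ties are broken by the smallest
#' (i, j) vertex-index pair so results are deterministic across platforms.
#'
#' @param contour a [disc_contour].
#' @return list with `endpoints` (2 x 2 matrix, rows = the two vertices),
#'   `length` (mm), `indices` (the vertex indices).
#' @export
longest_chord <- function(contour) {
  stopifnot(inherits(contour, "disc_contour"))
  pts <- contour$points
  D <- as.matrix(stats::dist(pts))
  m <- max(D)
  if (m <= 0) stop("contour '", contour$source_id, "': zero extent")
  hit <- which(D == m, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- hit[1, 1]; j <- hit[1, 2]
  list(endpoints = pts[c(i, j), , drop = FALSE], length = m,
       indices = c(i, j))
}

#' Shortest disc diameter (perpendicular caliper width)
#'
#' The shortest diameter (SD) is the width of the contour perpendicular to
#' the longest chord: the extent (max minus min) of vertex projections onto
#' the direction orthogonal to `direction`. For an elliptical disc this is
#' exactly the minor axis, and it always crosses the long axis, consistent
#' with defining the disc center at the intersection of the two diameters.
#'
#' @param contour a [disc_contour].
#' @param direction unit vector of the longest chord.
#' @return width in mm; never exceeds the longest chord length.
#' @export
shortest_diameter <- function(contour, direction) {
  stopifnot(inherits(contour, "disc_contour"))
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero-length axis direction")
  d <- direction / nrm
  perp <- c(-d[2], d[1])
  proj <- contour$points %*% perp
  max(proj) - min(proj)
}

#' Disc center
#'
#' Midpoint of the longest chord; for an elliptical disc this coincides with
#' the analytic center and with the intersection of the longest and shortest
#' diameters.
#'
#' @param contour a [disc_contour].
#' @return named numeric c(x, y) in mm.
#' @export
disc_center <- function(contour) {
  lc <- longest_chord(contour)
  c(x = mean(lc$endpoints[, 1]), y = mean(lc$endpoints[, 2]))
}

#' Disc tilt ratio
#'
#' Minimum-to-maximum disc diameter: shortest diameter divided by longest
#' chord length. 1 for a circular disc; 0.80 or less defines a tilted disc.
#'
#' @param contour a [disc_contour].
#' @return dimensionless ratio in (0, 1].
#' @export
tilt_ratio <- function(contour) {
  lc <- longest_chord(contour)
  d <- (lc$endpoints[2, ] - lc$endpoints[1, ]) / lc$length
  sd_ <- shortest_diameter(contour, d)
  sd_ / lc$length
}

#' Signed disc rotation degree
#'
#' The rotation degree is the acute signed angle between the disc's longest
#' axis and the reference line perpendicular to the fovea-disc ("horizontal")
#' line. Let h be the unit vector from disc center to fovea and r its
#' perpendicular oriented superiorly (+y component positive; +x if the
#' fovea-disc line is vertical). The long axis is oriented toward its
#' superior endpoint (larger projection on r); the returned angle is positive
#' when that superior endpoint deviates toward the fovea (temporal) side --
#' inferior rotation -- and negative when it deviates nasally -- superior
#' rotation. The rule is anchored on the fovea, so no laterality flag is
#' needed and the same code handles OD and OS.
#'
#' Near-circular discs have no meaningful axis: when the longest and
#' shortest diameters differ by less than `degenerate_tol` mm the angle is
#' reported as 0 with attribute `degenerate_axis = TRUE`.
#'
#' @param contour a [disc_contour].
#' @param fovea a [fovea_location] (or length-2 numeric, mm).
#' @param degenerate_tol axis-length difference (mm) below which the disc is
#'   treated as circular.
#' @return angle in degrees in \[-90, 90\], with attribute `degenerate_axis`.
#' @export
rotation_degree <- function(contour, fovea, degenerate_tol = 1e-6) {
  if (is.numeric(fovea)) fovea <- fovea_location(fovea)
  stopifnot(inherits(contour, "disc_contour"),
            inherits(fovea, "fovea_location"))
  lc <- longest_chord(contour)
  ctr <- c(mean(lc$endpoints[, 1]), mean(lc$endpoints[, 2]))
  h <- unname(fovea$point) - ctr
  hn <- sqrt(sum(h^2))
  if (hn < .Machine$double.eps^0.5)
    stop("fovea coincides with disc center: rotation reference undefined")
  if (hn <= lc$length / 2)
    warning("fovea lies inside the disc's longest radius; check inputs")
  h <- h / hn
  sd_ <- shortest_diameter(contour, lc$endpoints[2, ] - lc$endpoints[1, ])
  if (lc$length - sd_ < degenerate_tol)
    return(structure(0, degenerate_axis = TRUE))
  # reference perpendicular of the fovea-disc line, anchored to the fovea
  # alone (for a temporal fovea it points superior); keeps the measure
  # invariant under any rigid motion of the whole scene
  r <- c(h[2], -h[1])
  d <- (lc$endpoints[2, ] - lc$endpoints[1, ]) / lc$length
  if (sum(d * r) < 0) d <- -d   # orient toward the superior endpoint
  ang <- atan2(sum(d * h), sum(d * r)) * 180 / pi
  structure(unname(ang), degenerate_axis = FALSE)
}

#' Classify disc tilt
#'
#' A disc with tilt ratio of 0.80 or less is tilted; greater than 0.80 is
#' non-tilted.
#'
#' @param ratio tilt ratio(s) in (0, 1].
#' @return character vector, `"tilted"` or `"non_tilted"`.
#' @export
classify_tilt <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0 | ratio > 1))
    stop("tilt ratio must lie in (0, 1]")
  ifelse(ratio <= 0.80, "tilted", "non_tilted")
}

#' Classify disc rotation
#'
#' Rotation greater than +15 degrees is inferior rotation, lower than -15
#' degrees superior rotation, otherwise non-rotation (the +/-15 boundary is
#' non-rotation: "greater than" is strict).
#'
#' @param deg rotation degree(s) in \[-90, 90\].
#' @return character vector: `"superior"`, `"non_rotation"` or `"inferior"`.
#' @export
classify_rotation <- function(deg) {
  if (any(!is.finite(deg) | deg < -90 | deg > 90))
    stop("rotation degree must lie in [-90, 90]")
  ifelse(deg > 15, "inferior", ifelse(deg < -15, "superior", "non_rotation"))
}

#' Full disc morphometry
#'
#' Computes diameters, center, tilt ratio, signed rotation degree and the
#' tilt/rotation classifications for one disc contour.
#'
#' @param contour a [disc_contour].
#' @param fovea a [fovea_location] (or length-2 numeric, mm).
#' @param tilt_cutoff tilt ratio at or below which a disc is tilted.
#' @param rotation_cutoff absolute rotation (degrees) beyond which a disc is
#'   rotated.
#' @return object of class `morphometry_result`: a list with `tilt_ratio`,
#'   `rotation_deg`, `long_mm`, `short_mm`, `center`, `long_endpoints`,
#'   `tilt_class`, `rotation_class`, `degenerate_axis`, `source_id`,
#'   `laterality`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' ell <- disc_contour(cbind(0.9 * cos(th), 0.72 * sin(th)))
#' morphometry(ell, fovea_location(-4, 0))
#' @export
morphometry <- function(contour, fovea, tilt_cutoff = 0.80,
                        rotation_cutoff = 15) {
  if (is.numeric(fovea)) fovea <- fovea_location(fovea)
  lc <- longest_chord(contour)
  d <- (lc$endpoints[2, ] - lc$endpoints[1, ]) / lc$length
  sd_ <- shortest_diameter(contour, d)
  rot <- rotation_degree(contour, fovea)
  ratio <- sd_ / lc$length
  res <- list(
    tilt_ratio = ratio,
    rotation_deg = as.numeric(rot),
    long_mm = lc$length,
    short_mm = sd_,
    center = c(x = mean(lc$endpoints[, 1]), y = mean(lc$endpoints[, 2])),
    long_endpoints = lc$endpoints,
    tilt_class = ifelse(ratio <= tilt_cutoff, "tilted", "non_tilted"),
    rotation_class = classify_rotation_cutoff(as.numeric(rot), rotation_cutoff),
    degenerate_axis = isTRUE(attr(rot, "degenerate_axis")),
    source_id = contour$source_id,
    laterality = contour$laterality
  )
  class(res) <- "morphometry_result"
  res
}

classify_rotation_cutoff <- function(deg, cutoff) {
  ifelse(deg > cutoff, "inferior",
         ifelse(deg < -cutoff, "superior", "non_rotation"))
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(
    "<morphometry '%s'> %s\n  LD %.3f mm, SD %.3f mm, tilt ratio %.3f (%s)\n  rotation %+.2f deg (%s)%s\n",
    x$source_id, x$laterality, x$long_mm, x$short_mm, x$tilt_ratio,
    x$tilt_class, x$rotation_deg, x$rotation_class,
    if (x$degenerate_axis) " [degenerate axis]" else ""))
  invisible(x)
}

#' @rdname morphometry
#' @param x a `morphometry_result`.
#' @param ... unused.
#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(source_id = x$source_id, laterality = x$laterality,
             tilt_ratio = x$tilt_ratio, rotation_deg = x$rotation_deg,
             long_mm = x$long_mm, short_mm = x$short_mm,
             center_x = unname(x$center["x"]), center_y = unname(x$center["y"]),
             tilt_class = x$tilt_class, rotation_class = x$rotation_class,
             degenerate_axis = x$degenerate_axis,
             stringsAsFactors = FALSE)
}
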