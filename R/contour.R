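#' Optic disc contour
#'
#' Construct a `disc_contour` object: an ordered, simple, closed polygon
#' tracing the optic disc border (inner margin of the scleral ring) in a
#' standardized millimetre frame. The frame is right-handed with +y pointing
#' superior; readers of pixel images (row index increasing downward) must
#' negate the row axis before building a contour.
#'
#' @param points numeric matrix (n x 2) or data.frame with columns x, y, in
#'   mm. The polygon is implicitly closed (last vertex joins the first); a
#'   duplicated closing vertex is dropped.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param source_id free-text identifier carried through to output tables.
#' @param check_simple verify the polygon has no self-intersections. The
#'   check is O(n^2) in vertex count; it is skipped automatically above
#'   `simple_check_max` vertices.
#' @param simple_check_max vertex count above which the self-intersection
#'   check is skipped (geometry operations remain valid; only the validation
#'   is elided).
#' @return an object of class `disc_contour` with elements `points`
#'   (n x 2 matrix), `laterality`, `source_id`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' circ <- disc_contour(cbind(cos(th), sin(th)), laterality = "OD")
#' tilt_ratio(circ)
#' @export
disc_contour <- function(points, laterality = c("OD", "OS"),
                         source_id = "contour", check_simple = TRUE,
                         simple_check_max = 1000L) {
  laterality <- match.arg(laterality)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- unname(as.matrix(points))
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("contour '", source_id, "': points must be an n x 2 numeric matrix")
  if (!all(is.finite(points)))
    stop("contour '", source_id, "': non-finite coordinates")
  n <- nrow(points)
  if (n > 1L && isTRUE(all(points[1L, ] == points[n, ]))) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 8L)
    stop("contour '", source_id, "': needs >= 8 vertices, got ", n)
  per <- sum(sqrt(rowSums((points - points[c(2:n, 1L), ])^2)))
  if (per <= 0)
    stop("contour '", source_id, "': zero perimeter")
  if (max(points[, 1]) == min(points[, 1]) || max(points[, 2]) == min(points[, 2]))
    stop("contour '", source_id, "': degenerate (zero extent)")
  if (check_simple && n <= simple_check_max && !is_simple_polygon(points))
    stop("contour '", source_id, "': polygon self-intersects")
  structure(list(points = points, laterality = laterality,
                 source_id = source_id),
            class = "disc_contour")
}

#' @export
print.disc_contour <- function(x, ...) {
  cat(sprintf("<disc_contour '%s'> %s, %d vertices\n",
              x$source_id, x$laterality, nrow(x$points)))
  invisible(x)
}

# Self-intersection test over all non-adjacent edge pairs, vectorized.
# Proper crossings only; shared endpoints of adjacent edges are allowed.
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1L), , drop = FALSE]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  p <- a[i, , drop = FALSE]; r <- b[i, , drop = FALSE] - p
  q <- a[j, , drop = FALSE]; s <- b[j, , drop = FALSE] - q
  cross <- function(u, v) u[, 1] * v[, 2] - u[, 2] * v[, 1]
  denom <- cross(r, s)
  qp <- q - p
  t <- cross(qp, s) / denom
  u <- cross(qp, r) / denom
  hit <- is.finite(t) & is.finite(u) & t > 0 & t < 1 & u > 0 & u < 1
  !any(hit)
}

#' Fovea location
#'
#' Wrap the fovea coordinate (mm, same frame as the disc contour). The fovea
#' anchors the horizontal reference for disc rotation and must lie outside
#' the disc.
#'
#' @param x,y fovea coordinates in mm, or `x` a length-2 vector.
#' @return object of class `fovea_location`.
#' @export
fovea_location <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[2]; x <- x[1] }
  if (!is.finite(x) || !is.finite(y)) stop("fovea coordinates must be finite")
  structure(list(point = c(x = unname(x), y = unname(y))),
            class = "fovea_location")
}
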