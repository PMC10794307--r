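# Geometry fixtures and independent oracles used across test files.

# closed sampled ellipse, semi-axes a >= b, long axis rotated `angle_deg`
# counter-clockwise from +x, centered at `center`
make_ellipse <- function(a, b, n = 720, center = c(0, 0), angle_deg = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- angle_deg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(phi) - y * sin(phi),
        center[2] + x * sin(phi) + y * cos(phi))
}

# simple star-shaped polygon: random radii at sorted angles never
# self-intersect
rand_star_polygon <- function(n_vertices, r_range = c(0.5, 1.5)) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(r * cos(th), r * sin(th))
}

# brute-force all-pairs maximum distance (independent of stats::dist)
brute_max_chord <- function(pts) {
  n <- nrow(pts)
  dx <- outer(pts[, 1], pts[, 1], "-")
  dy <- outer(pts[, 2], pts[, 2], "-")
  sqrt(max(dx^2 + dy^2))
}

# projection-extent oracle: width of the point set along unit vector u
proj_extent <- function(pts, u) {
  p <- pts %*% (u / sqrt(sum(u^2)))
  max(p) - min(p)
}

# reflect points across the line through `origin` with direction `dir`
reflect_across <- function(pts, origin, dir) {
  d <- dir / sqrt(sum(dir^2))
  rel <- sweep(pts, 2, origin)
  along <- rel %*% d
  perp <- rel - outer(drop(along), d)
  sweep(outer(drop(along), d) - perp, 2, origin, "+")
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}
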