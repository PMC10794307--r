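test_that("longest chord matches known shapes and the brute-force oracle", {
  circ <- disc_contour(make_ellipse(1, 1, 360))
  expect_equal(longest_chord(circ)$length, 2, tolerance = 1e-3)

  sq <- disc_contour(rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5), c(1, 1),
                           c(0.5, 1), c(0, 1), c(0, 0.5)))
  lc <- longest_chord(sq)
  expect_equal(lc$length, sqrt(2), tolerance = 1e-12)
  expect_true(all(abs(lc$endpoints[1, ] - lc$endpoints[2, ]) > 0.9))

  ell <- disc_contour(make_ellipse(1.5, 1.0, 720))
  lc <- longest_chord(ell)
  expect_equal(lc$length, 3, tolerance = 1e-3)
  expect_lt(max(abs(abs(lc$endpoints[, 1]) - 1.5)), 2e-3)

  set.seed(101)
  for (i in 1:40) {
    pts <- rand_star_polygon(sample(8:400, 1))
    ctr <- disc_contour(pts, check_simple = FALSE)
    expect_equal(longest_chord(ctr)$length, brute_max_chord(pts),
                 tolerance = 1e-12)
  }
})

test_that("longest-chord ties break to the smallest vertex-index pair", {
  # regular octagon: diagonals (1,5) and (3,7) are exactly tied at length 2
  s <- sqrt(0.5)
  oct <- disc_contour(rbind(c(1, 0), c(s, s), c(0, 1), c(-s, s), c(-1, 0),
                            c(-s, -s), c(0, -1), c(s, -s)))
  expect_identical(longest_chord(oct)$indices, c(1L, 5L))
})

test_that("shortest diameter is the perpendicular projection extent", {
  ell <- disc_contour(make_ellipse(1.5, 1.0, 720))
  expect_equal(shortest_diameter(ell, c(1, 0)), 2, tolerance = 1e-3)

  circ <- disc_contour(make_ellipse(1, 1, 360))
  expect_equal(shortest_diameter(circ, c(0.6, 0.8)), 2, tolerance = 1e-3)

  sq <- rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5), c(1, 1), c(0.5, 1),
              c(0, 1), c(0, 0.5))
  sqc <- disc_contour(sq)
  d <- c(1, 1) / sqrt(2)
  expect_equal(shortest_diameter(sqc, d), proj_extent(sq, c(-1, 1)))
  expect_equal(shortest_diameter(sqc, d), sqrt(2), tolerance = 1e-12)
  expect_error(shortest_diameter(sqc, c(0, 0)), "zero-length")
})

test_that("disc center is the midpoint of the longest chord", {
  circ <- disc_contour(make_ellipse(1, 1, 360))
  expect_equal(unname(disc_center(circ)), c(0, 0), tolerance = 1e-3)
  ell <- disc_contour(make_ellipse(1.2, 0.8, 720, center = c(2, 3),
                                   angle_deg = 37))
  expect_equal(unname(disc_center(ell)), c(2, 3), tolerance = 2e-3)
})

test_that("tilt ratio recovers the semi-axis ratio of sampled ellipses", {
  expect_equal(tilt_ratio(disc_contour(make_ellipse(1, 1, 360))), 1,
               tolerance = 1e-3)
  expect_equal(tilt_ratio(disc_contour(make_ellipse(1.25, 1.0, 720))), 0.8,
               tolerance = 2e-3)
  expect_equal(tilt_ratio(disc_contour(make_ellipse(1, 0.74, 720))), 0.74,
               tolerance = 2e-3)
})

test_that("tilt ratio is invariant to translation, rotation and scale", {
  set.seed(7)
  for (i in 1:20) {
    pts <- rand_star_polygon(sample(10:200, 1))
    r0 <- tilt_ratio(disc_contour(pts, check_simple = FALSE))
    expect_lte(r0, 1)
    shift <- sweep(pts, 2, stats::runif(2, -5, 5), "+")
    expect_equal(tilt_ratio(disc_contour(shift, check_simple = FALSE)), r0,
                 tolerance = 1e-9)
    rotd <- pts %*% rot2(stats::runif(1, 0, 360))
    expect_equal(tilt_ratio(disc_contour(rotd, check_simple = FALSE)), r0,
                 tolerance = 1e-9)
    expect_equal(tilt_ratio(disc_contour(pts * stats::runif(1, 0.1, 10),
                                         check_simple = FALSE)), r0,
                 tolerance = 1e-9)
  }
})

test_that("rotation degree follows the fovea-anchored sign rule", {
  # long axis parallel to the reference line: no rotation
  ell <- disc_contour(make_ellipse(1, 0.8, 720, angle_deg = 90))
  expect_equal(as.numeric(rotation_degree(ell, c(-4, 0))), 0,
               tolerance = 0.5)

  # superior end leaning 20 deg toward the fovea (x < 0): inferior rotation
  lean <- disc_contour(make_ellipse(1, 0.8, 720, angle_deg = 110))
  expect_equal(as.numeric(rotation_degree(lean, c(-4, 0))), 20,
               tolerance = 0.5)

  # fovea below the image horizontal: the reference tilts with it
  vert <- disc_contour(make_ellipse(1, 0.8, 720, angle_deg = 90))
  expect_equal(as.numeric(rotation_degree(vert, c(-4, -0.3))),
               -atan2(0.3, 4) * 180 / pi, tolerance = 0.5)

  expect_error(rotation_degree(ell, c(0, 0)), "fovea")
})

test_that("rotation degree is invariant under rigid motion and flips under reflection", {
  set.seed(11)
  for (i in 1:15) {
    pts <- make_ellipse(1, stats::runif(1, 0.5, 0.9), 360,
                        angle_deg = stats::runif(1, 0, 180))
    fov <- c(-4.5, stats::runif(1, -1, 1))
    r0 <- as.numeric(rotation_degree(disc_contour(pts), fov))

    shift <- stats::runif(2, -3, 3)
    r_t <- rotation_degree(disc_contour(sweep(pts, 2, shift, "+")),
                           fov + shift)
    expect_equal(as.numeric(r_t), r0, tolerance = 1e-6)

    R <- rot2(stats::runif(1, 0, 360))
    r_r <- rotation_degree(disc_contour(pts %*% R), drop(fov %*% R))
    expect_equal(as.numeric(r_r), r0, tolerance = 1e-6)

    ctr <- disc_center(disc_contour(pts))
    refl <- reflect_across(pts, ctr, fov - ctr)
    r_m <- rotation_degree(disc_contour(refl), fov)
    expect_equal(as.numeric(r_m), -r0, tolerance = 1e-6)
  }
})

test_that("tilt and rotation classifications use the printed cutoffs", {
  expect_identical(classify_tilt(c(0.80, 0.81, 1.00)),
                   c("tilted", "non_tilted", "non_tilted"))
  expect_error(classify_tilt(1.2), "0, 1")
  expect_error(classify_tilt(0), "0, 1")
  expect_identical(classify_rotation(c(28.17, -29.2, 15, -15, 0)),
                   c("inferior", "superior", "non_rotation", "non_rotation",
                     "non_rotation"))
  expect_error(classify_rotation(95), "-90, 90")
})

test_that("morphometry composes the parts and flags degenerate axes", {
  m <- morphometry(disc_contour(make_ellipse(1, 1, 360)),
                   fovea_location(-4, 0))
  expect_equal(m$tilt_ratio, 1, tolerance = 1e-3)
  expect_identical(m$tilt_class, "non_tilted")
  expect_identical(m$rotation_class, "non_rotation")

  # perfect circle: axis undefined, rotation reported 0 with the flag
  th <- (0:15) * 2 * pi / 16
  circ16 <- disc_contour(cbind(cos(th), sin(th)))
  m2 <- morphometry(circ16, fovea_location(-4, 0))
  expect_true(m2$degenerate_axis)
  expect_identical(m2$rotation_deg, 0)

  df <- as.data.frame(m)
  expect_named(df, c("source_id", "laterality", "tilt_ratio", "rotation_deg",
                     "long_mm", "short_mm", "center_x", "center_y",
                     "tilt_class", "rotation_class", "degenerate_axis"))
})

test_that("contour validation rejects degenerate input", {
  expect_error(disc_contour(cbind(1:5, 1:5)), ">= 8 vertices")
  expect_error(disc_contour(cbind(rep(1, 10), rep(2, 10))), "perimeter|extent")
  expect_error(disc_contour(cbind(1:10, rep(0, 10))), "extent")
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2),
               c(-1, 3), c(-2, 2), c(-2, 1), c(-1, 0))
  expect_error(disc_contour(bow), "self-intersects")
})
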