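test_that("labeling uses 8-connectivity, keeps borders, filters by area", {
  expect_length(label_particles(matrix(FALSE, 6, 6)), 0)

  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[7:9, 6:8] <- TRUE
  comps <- label_particles(m)
  expect_length(comps, 2)
  expect_equal(vapply(comps, nrow, integer(1)), c(9L, 9L))

  diag_m <- matrix(FALSE, 8, 8)
  for (i in 1:6) diag_m[i, i] <- TRUE  # diagonal chain of single pixels
  expect_length(label_particles(diag_m), 1)

  border <- matrix(FALSE, 6, 6)
  border[1:2, 1:2] <- TRUE  # touches the image border
  expect_length(label_particles(border), 1)

  expect_length(label_particles(m, min_area = 10), 0)
  expect_length(label_particles(m, max_area = 8), 0)
  # ordering: topmost-then-leftmost first pixel
  expect_equal(comps[[1]][1, ], c(row = 2L, col = 2L))
})

test_that("a rasterized disk reproduces circle analytics", {
  m <- disk_mask(64, 64, 31, 31, 20)
  p <- measure_particle(label_particles(m)[[1]], matrix(100, 64, 64), 1)
  expect_gt(p$circularity, 0.9)
  expect_lte(p$circularity, 1)
  expect_gte(p$aspect_ratio, 1)
  expect_lt(p$aspect_ratio, 1.05)
  expect_lt(abs(p$area - pi * 400) / (pi * 400), 0.05)
  expect_gt(p$solidity, 0.98)
  expect_equal(p$roundness * p$aspect_ratio, 1, tolerance = 1e-6)
  expect_equal(p$x, 31, tolerance = 0.1)
  expect_equal(p$y, 31, tolerance = 0.1)
})

test_that("a rasterized ellipse reproduces axis, angle and area analytics", {
  m <- ellipse_mask(120, 120, 60, 60, 40, 10, 0)
  p <- measure_particle(label_particles(m)[[1]], matrix(50, 120, 120), 1)
  expect_lt(abs(p$aspect_ratio - 4) / 4, 0.05)
  ang <- min(p$angle, 180 - p$angle)
  expect_lt(ang, 2)
  expect_lt(abs(p$area - pi * 400) / (pi * 400), 0.05)
  expect_lt(abs(p$major - 80) / 80, 0.05)
  expect_gt(p$solidity, 0.98)
})

test_that("rotation shifts the reported angle and preserves size", {
  ref <- measure_particle(
    label_particles(ellipse_mask(120, 120, 60, 60, 35, 9, 0))[[1]],
    matrix(50, 120, 120), 1)
  for (phi in c(20, 65, 110)) {
    m <- ellipse_mask(120, 120, 60, 60, 35, 9, phi)
    p <- measure_particle(label_particles(m)[[1]], matrix(50, 120, 120), 1)
    dang <- abs(p$angle - phi %% 180)
    expect_lt(min(dang, 180 - dang), 3)
    expect_lt(abs(p$major - ref$major) / ref$major, 0.05)
    expect_lt(abs(p$area - ref$area) / ref$area, 0.05)
  }
})

test_that("measurements are scale equivariant", {
  comp <- label_particles(ellipse_mask(80, 80, 40, 40, 25, 12, 30))[[1]]
  g <- matrix(77, 80, 80)
  p1 <- measure_particle(comp, g, 1)
  p2 <- measure_particle(comp, g, 2)
  expect_equal(p2$area, 4 * p1$area)
  expect_equal(p2$perimeter, 2 * p1$perimeter)
  expect_equal(p2$major, 2 * p1$major)
  expect_equal(p2$minor, 2 * p1$minor)
  for (col in c("circularity", "aspect_ratio", "roundness", "solidity",
                "angle", "x", "y", "mean_grey")) {
    expect_equal(p2[[col]], p1[[col]], info = col)
  }
})

test_that("gray statistics come from the measured frame and are ordered", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  g <- matrix(0, 8, 8); g[3:5, 3:5] <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  p <- measure_particle(label_particles(m)[[1]], g, 1)
  expect_equal(p$min_grey, 10)
  expect_equal(p$max_grey, 90)
  expect_equal(p$mean_grey, 50)
  expect_true(p$min_grey <= p$mean_grey && p$mean_grey <= p$max_grey)
})

test_that("degenerate single-pixel components get a floored minor axis", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  p <- measure_particle(label_particles(m)[[1]], matrix(9, 5, 5), 1)
  expect_true(all(is.finite(unlist(p))))
  # area-matched disc of one pixel: diameter 2/sqrt(pi) ~ 1.13 px
  expect_gte(p$minor, 1)
  expect_lte(p$minor, 1.2)
  expect_equal(p$aspect_ratio, 1)
  expect_true(attr(p, "degenerate"))
  expect_equal(p$area, 1)
  expect_equal(p$perimeter, 4)
})

test_that("locate_and_measure yields the exact column contract in order", {
  s <- dot_stack(n_frames = 5, step = 10)
  parts <- locate_and_measure_particles(
    s, segmentation_params(offset = 1, threshold = 100, min_area = 1))
  expect_identical(names(parts),
                   c("video", "frame", "x", "y", "area", "mean_grey",
                     "min_grey", "max_grey", "perimeter", "major", "minor",
                     "angle", "circularity", "aspect_ratio", "roundness",
                     "solidity"))
  expect_equal(nrow(parts), 4)  # one detection per difference frame
  expect_false(is.unsorted(parts$frame))
  expect_true(all(parts$video == "dot"))
  # x advances with the dot
  expect_true(all(diff(parts$x) > 0))
  # gray source switch: raw frame has the dot value, difference is lower
  praw <- locate_and_measure_particles(
    s, segmentation_params(offset = 1, threshold = 100, min_area = 1),
    grey_source = "raw")
  expect_true(all(praw$max_grey == 200))
  expect_true(all(parts$max_grey <= 200 - 10))
})
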