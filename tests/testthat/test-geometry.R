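test_that("circle tangents follow theta + pi/2 and segments are straight", {
  g <- make_geometry("circle", r = 500)
  L <- g$contours[[1]]$length
  expect_equal(L, 2 * pi * 500, tolerance = 1e-3)
  # tangent at several polar angles; axis distance tolerance reflects the
  # polyline discretization
  for (th in c(0, pi / 4, pi / 2, 1.3, 2.8)) {
    s <- th * 500
    expect_lt(axis_dist(tangent_angle(g, s), (th + pi / 2) %% pi), 0.02)
  }
  seg <- make_geometry("segment", length = 1000, angle = 0)
  s_grid <- seq(0, 1000, by = 100)
  expect_true(all(axis_dist(tangent_angle(seg, s_grid), 0) < 1e-12))
  tilted <- make_geometry("segment", length = 800, angle = 2.1)
  expect_true(all(axis_dist(tangent_angle(tilted, c(0, 400, 800)),
                            2.1 %% pi) < 1e-12))
})

test_that("crossing filaments carry the two requested tangents", {
  g <- make_geometry("crossing_filaments", angles = c(0, pi / 3),
                     length = 1500)
  expect_length(g$contours, 2)
  expect_true(all(axis_dist(g$contours[[1]]$seg_tan, 0) < 1e-12))
  expect_true(all(axis_dist(g$contours[[2]]$seg_tan, pi / 3) < 1e-12))
  # both polylines pass through the shared centre
  mids <- lapply(g$contours, function(ct) point_at_s(ct, ct$length / 2))
  expect_equal(mids[[1]], mids[[2]], tolerance = 1e-9)
})

test_that("two_membranes builds parallel contours at the stated gap", {
  g <- make_geometry("two_membranes", length = 2000, gap = 150, angle = 0.4)
  expect_length(g$contours, 2)
  p1 <- point_at_s(g$contours[[1]], 1000)
  p2 <- point_at_s(g$contours[[2]], 1000)
  expect_equal(sqrt(sum((p1 - p2)^2)), 150, tolerance = 1e-9)
  expect_true(all(axis_dist(g$contours[[1]]$seg_tan, 0.4) < 1e-12))
})

test_that("spinehead contour is open with a head and a neck", {
  g <- make_geometry("spinehead", head_radius = 250, neck_width = 120,
                     neck_length = 400)
  ct <- g$contours[[1]]
  expect_false(ct$closed)
  expect_gt(ct$length, 2 * pi * 250 * 0.7) # most of the head plus the neck
  expect_error(make_geometry("spinehead", head_radius = 100,
                             neck_width = 300, neck_length = 100),
               "neck_width")
})

test_that("non-positive sizes are rejected", {
  expect_error(make_geometry("circle", r = -5), "positive")
  expect_error(make_geometry("segment", length = 0), "positive")
  expect_error(make_geometry("two_membranes", length = 100, gap = -1),
               "positive")
})

test_that("arc-length bookkeeping is consistent on closed contours", {
  g <- make_geometry("circle", r = 300)
  ct <- g$contours[[1]]
  # wrapping: s and s + L are the same point
  p <- point_at_s(ct, 123)
  pw <- point_at_s(ct, 123 + ct$length)
  expect_equal(p, pw, tolerance = 1e-9)
  expect_equal(tangent_angle(g, 123), tangent_angle(g, 123 + ct$length))
})
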