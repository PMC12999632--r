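test_that("circumcircle through three points is exact and permutation invariant", {
  # symmetric circumcircle
  c1 <- circle_from_three_points(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(unname(c1$center[c("x", "z")]), c(1, 1))
  expect_equal(c1$radius, sqrt(2))
  # unit circle
  c2 <- circle_from_three_points(c(-1, 0), c(0, 1), c(1, 0))
  expect_equal(unname(c2$center[c("x", "z")]), c(0, 0))
  expect_equal(c2$radius, 1)
  # property: equidistance and permutation invariance on random triples
  set.seed(11)
  for (i in 1:50) {
    pts <- matrix(rnorm(6, sd = 10), 3, 2)
    area2 <- (pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
      (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2])
    if (abs(area2) < 1e-3) next
    cc <- circle_from_three_points(pts[1, ], pts[2, ], pts[3, ])
    d <- sqrt((pts[, 1] - cc$center["x"])^2 + (pts[, 2] - cc$center["z"])^2)
    expect_true(all(abs(d - cc$radius) < 1e-9))
    cp <- circle_from_three_points(pts[3, ], pts[1, ], pts[2, ])
    expect_equal(cp$center, cc$center)
    expect_equal(cp$radius, cc$radius)
  }
})

test_that("collinear or duplicate points give a degenerate-geometry error", {
  expect_error(circle_from_three_points(c(0, 0), c(1, 1), c(2, 2)),
               class = "sarscan_degenerate_geometry")
  expect_error(circle_from_three_points(c(1, 2), c(1, 2), c(3, 4)),
               class = "sarscan_degenerate_geometry")
})

test_that("robot/measurement frame conversion round-trips and flips z", {
  fr <- coordinate_frame(origin_in_robot = c(10, 20, 5))
  expect_equal(unname(to_measurement_frame(c(10, 20, 5), fr)), c(0, 0, 0))
  # robot z one below the origin maps to measurement depth +1
  expect_equal(unname(to_measurement_frame(c(10, 20, 4), fr))[3], 1)
  set.seed(7)
  p <- matrix(rnorm(300, sd = 20), ncol = 3)
  expect_equal(to_robot_frame(to_measurement_frame(p, fr), fr), p,
               tolerance = 1e-12, ignore_attr = TRUE)
  # no-flip frame keeps z
  fr2 <- coordinate_frame(c(0, 0, 0), z_sign_flip = FALSE)
  expect_equal(unname(to_measurement_frame(c(0, 0, 3), fr2))[3], 3)
})

test_that("surface coordinates: flat, cylinder arc length and invertibility", {
  expect_equal(unname(surface_coordinates(c(3, -2, 1), flat_surface())), c(3, -2, 1))
  cyl <- cylinder_surface(17.5)
  # point at angle 0.1 rad from the apex, 18.5 cm from the axis
  p <- c(18.5 * sin(0.1), 4, 18.5 * cos(0.1) - 17.5)
  sc <- surface_coordinates(p, cyl)
  expect_equal(unname(sc), c(17.5 * 0.1, 4, 1), tolerance = 1e-12)
  # apex on the contact surface
  expect_equal(unname(surface_coordinates(c(0, 2.5, 0), cyl)), c(0, 2.5, 0))
  # above the surface is an error
  expect_error(surface_coordinates(c(0, 0, -0.5), cyl), class = "sarscan_negative_depth")
  # invertibility on random surface coordinates
  set.seed(5)
  uvd <- cbind(runif(100, -20, 20), runif(100, -12, 12), runif(100, 0, 6))
  expect_equal(surface_coordinates(surface_point(uvd, cyl), cyl),
               `colnames<-`(uvd, c("u", "v", "depth")), tolerance = 1e-9)
})

test_that("flat geometry is the infinite-radius limit of the cylinder", {
  big <- cylinder_surface(1e6)
  pts <- cbind(x = seq(-15, 15, 2.5), y = 0, z = 1)
  sc_c <- surface_coordinates(pts, big)
  sc_f <- surface_coordinates(pts, flat_surface())
  expect_lt(max(abs(sc_c - sc_f)), 1e-3)
})

test_that("flat xy plans count points and anchor the grid at the origin", {
  fr <- default_frame(); bb <- test_bbox()
  plan <- build_scan_plan(flat_surface(), fr, bb, "xy_at_depth", 1)
  expect_equal(nrow(plan$points), 33 * 25)
  expect_true(all(plan$points$depth == 1))
  expect_true(any(plan$points$u == 0 & plan$points$v == 0))
  fine <- build_scan_plan(flat_surface(), fr, bb, "xy_at_depth", 0.25)
  expect_equal(nrow(fine$points), 129 * 97)
  # ~16-fold scan-time increase for a 4x finer grid, asymptotically
  expect_equal(nrow(fine$points) / nrow(plan$points), 15.2, tolerance = 0.01)
  # no duplicate points, all inside the bounding box
  expect_equal(anyDuplicated(plan$points[c("u", "v", "depth")]), 0L)
  expect_true(all(plan$points$u >= -16 & plan$points$u <= 16))
  expect_true(all(plan$points$v >= -12 & plan$points$v <= 12))
})

test_that("same-row consecutive points are separated by exactly the spacing", {
  plan <- build_scan_plan(flat_surface(), default_frame(), test_bbox(), "xy_at_depth", 1)
  p <- plan$points
  for (vv in unique(p$v)[c(1, 13, 25)]) {
    row <- p[p$v == vv, ]
    expect_equal(abs(diff(row$u)), rep(1, nrow(row) - 1))
  }
})

test_that("cylinder plans put reference-curve points on the offset cylinder", {
  cyl <- cylinder_surface(17.5)
  fr <- default_frame()
  plan <- build_scan_plan(cyl, fr, test_bbox(), "xz", 1)
  pts <- plan$points
  first_pass <- pts[abs(pts$depth - 1) < 1e-12, ]
  # emitted first, before any deeper point
  expect_equal(seq_len(nrow(first_pass)), which(abs(pts$depth - 1) < 1e-12))
  # radial distance from the cylinder axis (measurement (0, y, -17.5))
  r <- sqrt(first_pass$x_meas^2 + (first_pass$z_meas + 17.5)^2)
  expect_true(all(abs(r - 18.5) < 1e-6))
  # deeper rows in increasing depth order
  expect_true(all(diff(pts$depth) >= 0))
  # xy plan on the cylinder: every point on the offset cylinder
  plan_xy <- build_scan_plan(cyl, fr, test_bbox(), "xy_at_depth", 1)
  r2 <- sqrt(plan_xy$points$x_meas^2 + (plan_xy$points$z_meas + 17.5)^2)
  expect_true(all(abs(r2 - 18.5) < 1e-6))
})

test_that("degenerate plans error out", {
  fr <- default_frame()
  # no origin-anchored node falls inside this box at 1 cm spacing
  expect_error(build_scan_plan(flat_surface(), fr, bounding_box(c(0.2, 0.8), c(0.2, 0.8)),
                               "xy_at_depth", 1),
               class = "sarscan_empty_plan")
  expect_error(build_scan_plan(flat_surface(), fr, test_bbox(), "xz", 1,
                               depth_range = c(2, 6)),
               class = "sarscan_bad_depth_range")
  # arc extent beyond the quarter circle of a small cylinder
  expect_error(build_scan_plan(cylinder_surface(5), fr, test_bbox(), "xz", 1),
               class = "sarscan_out_of_workspace")
})

test_that("G-code emission and parsing round-trip the plan", {
  fr <- default_frame(); bb <- test_bbox()
  plan <- build_scan_plan(flat_surface(), fr, bb, "xy_at_depth", 1)
  gc <- emit_gcode(plan)
  expect_identical(gc[1:2], c("G21", "G90"))
  parsed <- parse_gcode(gc)
  expect_equal(parsed$n_read_markers, 825)
  expect_equal(parsed$points,
               unname(as.matrix(plan$points[c("x_robot", "y_robot", "z_robot")])),
               ignore_attr = TRUE)
  expect_equal(parsed$dwell_s, 0.8)
  expect_equal(parsed$n_readings, 3L)
  # single-point plan body: move, dwell, read marker
  one <- build_scan_plan(flat_surface(), fr, bounding_box(c(0, 0), c(0, 0)), "xy_at_depth", 1)
  gc1 <- emit_gcode(one)
  expect_length(gc1, 5)  # G21, G90, G1, G4, (READ)
  expect_match(gc1[4], "^G4 P0\\.8")
  expect_match(gc1[5], "^\\(READ n=3\\)$")
  # empty plan errors
  empty <- one; empty$points <- empty$points[0, ]
  expect_error(emit_gcode(empty), class = "sarscan_empty_plan")
})

test_that("scan plans round-trip through JSON", {
  plan <- build_scan_plan(cylinder_surface(17.5), coordinate_frame(c(25, 30, 12)),
                          bounding_box(c(-10, 10), c(-8, 8), c(0, 5)), "xz", 1)
  path <- tempfile(fileext = ".json")
  write_scan_plan(plan, path)
  back <- read_scan_plan(path)
  expect_equal(back$points, plan$points, tolerance = 1e-12)
  expect_equal(back$surface$radius, 17.5)
  expect_equal(back$frame$origin_in_robot, c(25, 30, 12))
  expect_equal(back$plane_kind, "xz")
})
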