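test_that("bilinear interpolation reproduces constants, linear fields and nodes", {
  rec_const <- field_record(function(u, v, d) 100, u = c(0, 10), v = c(0, 10))
  g <- interpolate_plane(rec_const)
  expect_true(all(abs(g$values - 100) < 1e-12))
  expect_equal(g$spacing, 0.1)
  # linear field u + v is reproduced everywhere, not just at nodes
  rec_lin <- field_record(function(u, v, d) u + v, u = seq(0, 8, 2), v = seq(0, 8, 2))
  gl <- interpolate_plane(rec_lin)
  expected <- outer(gl$a1, gl$a2, `+`)
  expect_lt(max(abs(gl$values - expected)), 1e-9)
  # measurement points are reproduced exactly at their own locations
  m <- scenario_preset("5H-flat-1.3")
  rec <- field_record(function(u, v, d) 100 * relative_sar(m, u, v, d))
  gg <- interpolate_plane(rec)
  iu <- match(rec$u, gg$a1); iv <- match(rec$v, gg$a2)
  expect_equal(gg$values[cbind(iu, iv)], rec$sar, tolerance = 1e-12)
})

test_that("interpolation rejects collinear and non-raster point clouds", {
  line <- data.frame(u = 0:5, v = 0, sar = 1)
  expect_error(interpolate_plane(line), class = "sarscan_collinear_points")
  scattered <- data.frame(u = c(0, 1, 0.5), v = c(0, 0, 1), sar = 1:3)
  expect_error(interpolate_plane(scattered), class = "sarscan_not_raster")
})

test_that("coarse and fine interpolations of a smooth field agree", {
  m <- scenario_preset("3H-flat-1.3")
  f <- function(u, v, d) 100 * relative_sar(m, u, v, d)
  fine <- interpolate_plane(field_record(f, u = seq(-16, 16, 0.25), v = seq(-12, 12, 0.25)))
  coarse <- interpolate_plane(field_record(f, u = seq(-16, 16, 1), v = seq(-12, 12, 1)))
  rms <- sqrt(mean((fine$values - coarse$values)^2))
  expect_lt(rms / 100, 0.015)
})

test_that("isolines of a cone are circles and regions nest across levels", {
  cone <- field_record(function(u, v, d) pmax(0, 100 * (1 - sqrt(u^2 + v^2) / 10)),
                       u = seq(-12, 12, 0.5), v = seq(-12, 12, 0.5))
  g <- interpolate_plane(cone)
  iso <- extract_isolines(g, levels = c(50, 70, 90, 98))
  p50 <- iso$sets[["50"]]$polylines[[1]]
  radii <- sqrt(p50$x^2 + p50$y^2)
  expect_true(all(abs(radii - 5) < 0.1))
  # monotone nesting of cell counts and containment
  n_cells <- vapply(iso$sets, `[[`, numeric(1), "n_cells")
  expect_true(all(diff(n_cells) < 0))
  r90 <- g$values >= 90
  r98 <- g$values >= 98
  expect_true(all(r90[r98]))
  expect_gt(sum(r98), 0)
  # a level above the maximum yields an empty set, not an error
  iso_hi <- extract_isolines(g, levels = 120)
  expect_equal(iso_hi$sets[["120"]]$n_cells, 0)
  expect_equal(iso_hi$sets[["120"]]$n_components, 0L)
})

test_that("EFS matches the Gaussian closed form across widths", {
  for (sig in c(2, 5, 8.876, 12)) {
    f <- function(u, v, d) 100 * exp(-u^2 / (2 * sig^2)) * exp(-v^2 / (2 * 5^2))
    g <- interpolate_plane(field_record(f))
    efs <- compute_efs(g)
    expect_equal(efs$efs_x, fwhm(sig), tolerance = 0.1 / fwhm(sig))
    expect_equal(efs$efs_y, fwhm(5), tolerance = 0.1 / fwhm(5))
    expect_equal(efs$dx, 0, tolerance = 0.05)
    expect_equal(efs$dy, 0, tolerance = 0.05)
  }
})

test_that("EFS is translation equivariant and handles uniform disks", {
  sigx <- 8.876; sigy <- 5.308
  f0 <- function(u, v, d) 100 * exp(-u^2 / (2 * sigx^2) - v^2 / (2 * sigy^2))
  ft <- function(u, v, d) f0(u - 0.8, v + 0.9, d)
  e0 <- compute_efs(interpolate_plane(field_record(f0)))
  et <- compute_efs(interpolate_plane(field_record(ft)))
  expect_equal(et$dx, 0.8, tolerance = 0.05)
  expect_equal(et$dy, -0.9, tolerance = 0.05)
  expect_equal(et$efs_x, e0$efs_x, tolerance = 0.1 / e0$efs_x)
  expect_equal(et$efs_y, e0$efs_y, tolerance = 0.1 / e0$efs_y)
  # uniform disk of radius 5: EFS 10 x 10 (finite sampling biases the sharp
  # edge outward by up to half a source cell)
  disk <- field_record(function(u, v, d) 100 * (sqrt(u^2 + v^2) <= 5),
                       u = seq(-8, 8, 0.1), v = seq(-8, 8, 0.1))
  ed <- compute_efs(interpolate_plane(disk))
  expect_equal(ed$efs_x, 10, tolerance = 0.15 / 10)
  expect_equal(ed$efs_y, 10, tolerance = 0.15 / 10)
})

test_that("EFS contour extremes agree with the >= 50% cell set within one cell", {
  m <- scenario_preset("5H-flat-2.5")  # split 50% region stresses the pooling
  for (mod in list(m, scenario_preset("3H-flat-1.3"))) {
    g <- interpolate_plane(field_record(function(u, v, d) 100 * relative_sar(mod, u, v, d)))
    efs <- compute_efs(g)
    region <- g$values >= 50
    idx <- which(region, arr.ind = TRUE)
    cell_x <- range(g$a1[idx[, 1]]); cell_y <- range(g$a2[idx[, 2]])
    # each extreme agrees within one fine cell, so the span within two
    expect_lt(abs(efs$efs_x - diff(cell_x)), 0.2 + 1e-9)
    expect_lt(abs(efs$efs_y - diff(cell_y)), 0.2 + 1e-9)
  }
})

test_that("EFS warns when the 50% region is truncated by the bounding box", {
  wide <- field_record(function(u, v, d) 100 * exp(-v^2 / (2 * 3^2)),
                       u = seq(-5, 5, 1), v = seq(-12, 12, 1))
  expect_warning(compute_efs(interpolate_plane(wide)), "truncated")
  flat0 <- field_record(function(u, v, d) 10)
  expect_error(suppressWarnings(compute_efs(interpolate_plane(flat0))),
               class = "sarscan_empty_region")
})

test_that("plane EPD matches exponential closed forms and censors pathologies", {
  # half-value depth scale 1.5 cm: EPD = 1.50 exactly
  f <- function(u, d) 100 * exp(-u^2 / (2 * 36)) * 2^(-(d - 1) / 1.5)
  # depth sampled at 0.25 cm so the linear-in-depth crossing is near-exact;
  # coarse 1 cm sampling carries an inherent chord offset (see vignette)
  make_plane <- function(f, depths = seq(1, 8, 0.25)) {
    g <- expand.grid(u = seq(-10, 10, 1), depth = depths)
    g$sar <- f(g$u, g$depth)
    structure(g, metadata = list(spacing_cm = 1), class = c("scan_record", "data.frame"))
  }
  g1 <- interpolate_plane(make_plane(f), axes = c("u", "depth"))
  epd <- compute_epd_from_plane(g1)
  expect_equal(epd$epd, 1.5, tolerance = 0.01)
  expect_false(epd$censored)
  expect_equal(epd$column, 0)
  # exponential closed form EPD = delta ln2 / 2 across delta
  for (delta in c(3, 7, 12)) {
    fd <- function(u, d) 100 * exp(-u^2 / (2 * 36)) * exp(-2 * (d - 1) / delta)
    gd <- interpolate_plane(make_plane(fd), axes = c("u", "depth"))
    ed <- compute_epd_from_plane(gd)
    expect_equal(ed$epd, delta * log(2) / 2, tolerance = 0.05 / (delta * log(2) / 2))
  }
  # from-interface convention adds the reference depth
  epd_if <- compute_epd_from_plane(g1, convention = "from_interface")
  expect_equal(epd_if$epd, 2.5, tolerance = 0.01)
  # monotone-increasing column never crosses: censored
  finc <- function(u, d) 50 * exp(-u^2 / 80) * (1 + 0.05 * (d - 1))
  expect_warning(ec <- compute_epd_from_plane(interpolate_plane(make_plane(finc),
                                                                axes = c("u", "depth"))),
                 "censored")
  expect_true(ec$censored)
  expect_true(is.na(ec$epd))
  # a plane without sufficient depth is rejected
  shallow <- interpolate_plane(make_plane(f, depths = seq(1, 3, 0.25)), axes = c("u", "depth"))
  expect_error(compute_epd_from_plane(shallow), class = "sarscan_too_shallow")
})

test_that("EPD max-SAR ties break towards the smallest |u|", {
  f <- function(u, d) 100 * 2^(-(d - 1) / 2) * (abs(u) <= 6)  # flat-topped
  g <- expand.grid(u = seq(-10, 10, 1), depth = 1:6)
  g$sar <- f(g$u, g$depth)
  rec <- structure(g, metadata = list(spacing_cm = 1), class = c("scan_record", "data.frame"))
  epd <- compute_epd_from_plane(interpolate_plane(rec, axes = c("u", "depth")))
  expect_equal(epd$column, 0)
})

test_that("Delta-EPD is identically zero for separable fields", {
  m <- applicator_model(kappa = 0, centre = c(0.8, -0.9))
  ses <- noiseless_session(m, "volume")
  vol <- build_sar_volume(ses$records$volume)
  dm <- compute_delta_epd(vol)
  expect_lt(max(abs(dm$delta)), 1e-9)
  expect_true(all(dm$region))
  expect_true(dm$x_axis_in_region)
  expect_true(dm$y_axis_in_region)
  expect_equal(dm$n_censored, 0)
})

test_that("Delta-EPD equals a brute-force per-column recomputation", {
  m <- scenario_preset("5H-flat-1.3")  # kappa > 0: non-separable
  ses <- noiseless_session(m, "volume")
  vol <- build_sar_volume(ses$records$volume)
  dm <- compute_delta_epd(vol)
  # independent brute force: own crossing arithmetic per column
  brute <- matrix(NA_real_, length(vol$u), length(vol$v))
  for (i in seq_along(vol$u)) {
    for (j in seq_along(vol$v)) {
      prof <- vol$values[i, j, ]
      target <- prof[1] / 2
      k <- which(prof <= target)[1]
      if (!is.na(k) && k > 1) {
        d <- vol$depth
        brute[i, j] <- d[k - 1] + (d[k] - d[k - 1]) * (prof[k - 1] - target) /
          (prof[k - 1] - prof[k]) - 1
      }
    }
  }
  expect_equal(dm$epd, brute, tolerance = 1e-12)
  i_max <- which(abs(vol$u - dm$max_sar_uv["u"]) < 1e-9)
  j_max <- which(abs(vol$v - dm$max_sar_uv["v"]) < 1e-9)
  expect_identical(dm$delta[i_max, j_max], 0)
  expect_equal(dm$delta, (brute - brute[i_max, j_max]) / brute[i_max, j_max] * 100,
               tolerance = 1e-12)
})

test_that("Delta-EPD errors when the max-SAR column is censored", {
  g <- expand.grid(u = -2:2, v = -2:2, depth = 1:6)
  g$sar <- 100 * exp(-(g$u^2 + g$v^2) / 20)  # no depth decay at all
  rec <- structure(g, metadata = list(spacing_cm = 1), class = c("scan_record", "data.frame"))
  vol <- build_sar_volume(rec)
  expect_error(compute_delta_epd(vol), class = "sarscan_too_shallow")
})

test_that("resampling is a strict phase-anchored subset", {
  m <- scenario_preset("3H-flat-1.3")
  fine <- field_record(function(u, v, d) 100 * relative_sar(m, u, v, d),
                       u = seq(-16, 16, 0.25), v = seq(-12, 12, 0.25))
  expect_equal(nrow(fine), 129 * 97)
  sub1 <- resample_plane(fine, 1, 0.25)
  expect_equal(nrow(sub1), 33 * 25)
  expect_true(all(sub1$u %% 1 == 0))
  # identity at equal spacing
  expect_equal(nrow(resample_plane(fine, 0.25, 0.25)), nrow(fine))
  # composition 0.25 -> 1 -> 2 equals direct 0.25 -> 2
  sub2a <- resample_plane(sub1, 2, 1)
  sub2b <- resample_plane(fine, 2, 0.25)
  expect_equal(sub2a$sar, sub2b$sar)
  expect_error(resample_plane(fine, 0.3, 0.25), class = "sarscan_incommensurate")
})

test_that("the Delta-EPD threshold inversion gives absolute depth differences", {
  expect_equal(delta_epd_threshold(5, 2.6), 0.13)
  expect_equal(delta_epd_threshold(0, 2.6), 0)
})
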