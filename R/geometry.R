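#' Coordinate frames, contact-surface geometry and scan plans
#'
#' The measurement coordinate system follows the IEC 61217 fixed reference
#' frame used in radiotherapy QA, with its origin at the centre of the
#' applicator projected onto the bolus--phantom interface and the z axis
#' re-signed so that z increases with depth into the phantom. The robot has
#' its own fixed frame; [to_measurement_frame()] and [to_robot_frame()]
#' convert between the two. All lengths are centimetres; millimetres appear
#' only inside emitted G-code text.
#'
#' @name sarscan-geometry
NULL

#' Construct a 3-D point
#'
#' Points are plain named numeric vectors `c(x, y, z)` in centimetres;
#' functions accept either a single point or an `n x 3` matrix.
#'
#' @param x,y,z Coordinates in cm. Must be finite.
#' @return Named numeric vector of length 3.
#' @export
point3 <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) stop_sarscan("point3 components must be finite", class = "sarscan_bad_point")
  p
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(unname(p))
  }
  matrix(as.numeric(p), ncol = 3L)
}

#' Coordinate frame linking robot and measurement coordinates
#'
#' @param origin_in_robot Robot coordinates (cm) of the measurement origin,
#'   i.e. the centre of the applicator at the bolus--phantom interface.
#' @param z_sign_flip If `TRUE` (default) the measurement z axis points in the
#'   opposite direction to the robot z axis so that measurement z increases
#'   with depth.
#' @return An object of class `coordinate_frame`.
#' @export
coordinate_frame <- function(origin_in_robot = c(0, 0, 0), z_sign_flip = TRUE) {
  origin_in_robot <- as.numeric(origin_in_robot)
  stopifnot(length(origin_in_robot) == 3L, all(is.finite(origin_in_robot)))
  structure(list(origin_in_robot = origin_in_robot, z_sign_flip = isTRUE(z_sign_flip)),
            class = "coordinate_frame")
}

#' Convert robot coordinates to measurement coordinates (and back)
#'
#' @param p Point (length-3 vector) or `n x 3` matrix, in cm.
#' @param frame A [coordinate_frame()].
#' @return Point(s) in the other frame, same shape as the input.
#' @export
to_measurement_frame <- function(p, frame) {
  stopifnot(inherits(frame, "coordinate_frame"))
  was_vec <- !is.matrix(p)
  m <- as_point_matrix(p)
  m <- sweep(m, 2L, frame$origin_in_robot)
  if (frame$z_sign_flip) m[, 3L] <- -m[, 3L]
  if (was_vec) setNames(drop(m), c("x", "y", "z")) else {
    colnames(m) <- c("x", "y", "z"); m
  }
}

#' @rdname to_measurement_frame
#' @export
to_robot_frame <- function(p, frame) {
  stopifnot(inherits(frame, "coordinate_frame"))
  was_vec <- !is.matrix(p)
  m <- as_point_matrix(p)
  if (frame$z_sign_flip) m[, 3L] <- -m[, 3L]
  m <- sweep(m, 2L, frame$origin_in_robot, FUN = "+")
  if (was_vec) setNames(drop(m), c("x", "y", "z")) else {
    colnames(m) <- c("x", "y", "z"); m
  }
}

#' Contact surface between applicator/bolus and phantom
#'
#' Flat surfaces are the z = 0 plane of the measurement frame. Cylindrical
#' surfaces model a curved contact sheet whose axis runs along the
#' measurement y axis, with the apex (lowest point of the trough) at the
#' measurement origin; phantom depth increases radially outward from the
#' axis, so a point at depth `d` lies at distance `radius + d` from the axis.
#'
#' @param radius Curvature radius of the contact surface in cm (> 0).
#' @param circle_center Optional robot coordinates of the fitted circle
#'   centre (kept for provenance when the surface comes from
#'   [circle_from_three_points()]).
#' @return An object of class `contact_surface`.
#' @export
cylinder_surface <- function(radius, circle_center = NULL) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius), radius > 0)
  structure(list(kind = "cylinder", radius = radius, circle_center = circle_center),
            class = "contact_surface")
}

#' @rdname cylinder_surface
#' @export
flat_surface <- function() {
  structure(list(kind = "flat", radius = Inf, circle_center = NULL),
            class = "contact_surface")
}

#' Bounding box of a scan, in surface coordinates
#'
#' Limits are expressed in surface coordinates: `xlim` along the contact
#' surface (arc length for curved setups), `ylim` along the cylinder axis,
#' `zlim` in depth below the contact surface.
#'
#' @param xlim,ylim,zlim Numeric length-2 `c(min, max)` in cm.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(xlim, ylim, zlim = c(0, 6)) {
  chk <- function(l, nm) {
    stopifnot(length(l) == 2L, all(is.finite(l)))
    if (l[1] > l[2]) stop_sarscan("bounding_box ", nm, ": min > max", class = "sarscan_bad_bbox")
    as.numeric(l)
  }
  structure(list(xlim = chk(xlim, "xlim"), ylim = chk(ylim, "ylim"), zlim = chk(zlim, "zlim")),
            class = "bounding_box")
}

#' Circumcircle through three points in the xz-plane
#'
#' Used to recover the virtual circle whose circumference contains the 1 cm
#' depth curve under a curved contact surface: the user jogs the probe to
#' three points at equal depth and the fitted circle determines the cylinder
#' axis and radius.
#'
#' @param p1,p2,p3 Points, either length-2 `c(x, z)` or length-3 `c(x, y, z)`
#'   (the y component is ignored for the fit and averaged for the centre).
#' @return List with `center` (point3, y = mean input y) and `radius` (cm).
#' @export
circle_from_three_points <- function(p1, p2, p3) {
  take <- function(p) {
    p <- as.numeric(p)
    if (length(p) == 2L) c(p[1], 0, p[2]) else if (length(p) == 3L) p else
      stop_sarscan("points must have 2 (x,z) or 3 (x,y,z) components", class = "sarscan_bad_point")
  }
  P <- rbind(take(p1), take(p2), take(p3))
  x <- P[, 1]; z <- P[, 3]
  # twice the signed triangle area in the xz-plane
  area2 <- (x[2] - x[1]) * (z[3] - z[1]) - (x[3] - x[1]) * (z[2] - z[1])
  if (abs(area2) < 2e-9) {
    stop_sarscan(
      "degenerate geometry: points (", paste(sprintf("%.4g", x), sprintf("%.4g", z), sep = ",", collapse = "), ("),
      ") are collinear or coincident in the xz-plane",
      class = "sarscan_degenerate_geometry")
  }
  # perpendicular-bisector solution
  d1 <- x[1]^2 + z[1]^2; d2 <- x[2]^2 + z[2]^2; d3 <- x[3]^2 + z[3]^2
  ux <- (d1 * (z[2] - z[3]) + d2 * (z[3] - z[1]) + d3 * (z[1] - z[2])) / (2 * ((x[1] * (z[2] - z[3]) + x[2] * (z[3] - z[1]) + x[3] * (z[1] - z[2]))))
  uz <- (d1 * (x[3] - x[2]) + d2 * (x[1] - x[3]) + d3 * (x[2] - x[1])) / (2 * ((x[1] * (z[2] - z[3]) + x[2] * (z[3] - z[1]) + x[3] * (z[1] - z[2]))))
  r <- sqrt((x[1] - ux)^2 + (z[1] - uz)^2)
  list(center = point3(ux, mean(P[, 2]), uz), radius = r)
}

#' Surface coordinates of a point
#'
#' Maps a point in measurement coordinates onto `(u, v, depth)` surface
#' coordinates: `u` is the signed arc length along the contact surface
#' (plain x for flat setups), `v` the position along the cylinder axis (y),
#' and `depth` the distance below the contact surface.
#'
#' @param p Measurement-frame point or `n x 3` matrix (cm).
#' @param surface A [flat_surface()] or [cylinder_surface()].
#' @param tol Tolerance for the negative-depth check (cm).
#' @return Matrix (or named vector) with columns `u`, `v`, `depth`.
#' @export
surface_coordinates <- function(p, surface, tol = 1e-9) {
  stopifnot(inherits(surface, "contact_surface"))
  was_vec <- !is.matrix(p)
  m <- as_point_matrix(p)
  if (surface$kind == "flat") {
    out <- cbind(u = m[, 1], v = m[, 2], depth = m[, 3])
  } else {
    R <- surface$radius
    dx <- m[, 1]; dz <- m[, 3] + R  # axis at measurement (0, y, -R)
    r <- sqrt(dx^2 + dz^2)
    theta <- atan2(dx, dz)
    out <- cbind(u = R * theta, v = m[, 2], depth = r - R)
  }
  if (any(out[, "depth"] < -tol)) {
    stop_sarscan("point above the contact surface (negative depth)",
                 class = "sarscan_negative_depth")
  }
  if (was_vec) drop(out) else out
}

#' @rdname surface_coordinates
#' @param uvd Surface coordinates `(u, v, depth)` vector or matrix.
#' @export
surface_point <- function(uvd, surface) {
  stopifnot(inherits(surface, "contact_surface"))
  was_vec <- !is.matrix(uvd)
  m <- if (is.matrix(uvd)) unname(uvd) else matrix(as.numeric(uvd), ncol = 3L)
  if (surface$kind == "flat") {
    out <- cbind(x = m[, 1], y = m[, 2], z = m[, 3])
  } else {
    R <- surface$radius
    theta <- m[, 1] / R
    rr <- R + m[, 3]
    out <- cbind(x = rr * sin(theta), y = m[, 2], z = rr * cos(theta) - R)
  }
  if (was_vec) drop(out) else out
}

plane_kinds <- c("xy_at_depth", "xz", "yz", "volume")

#' Build a scan plan
#'
#' Generates the ordered list of measurement points for one plane or volume
#' scan. Grid nodes sit at integer multiples of `spacing` from the
#' measurement origin, so the applicator centre is always sampled and coarse
#' grids are strict subsets of fine ones. For depth scans (`xz`, `yz`,
#' `volume`) the points on the reference curve at `depth_reference`
#' (following the curvature) are emitted first, then the remaining rows in
#' boustrophedon order by increasing depth.
#'
#' @param surface A [contact_surface][flat_surface] object.
#' @param frame A [coordinate_frame()].
#' @param bbox A [bounding_box()] in surface coordinates.
#' @param plane_kind One of `"xy_at_depth"`, `"xz"`, `"yz"`, `"volume"`.
#' @param spacing Grid spacing in cm (> 0); also the depth step.
#' @param depth_range `c(min, max)` depth in cm for depth scans; must start
#'   at `depth_reference`.
#' @param depth_reference Reference depth of the xy-plane (default 1 cm).
#' @param dwell_s Dwell before reading, seconds (default 0.8).
#' @param n_readings Voltage readings per point (default 3).
#' @return An object of class `scan_plan` with a `points` data frame holding
#'   surface, measurement and robot coordinates in scan order.
#' @export
build_scan_plan <- function(surface, frame, bbox, plane_kind = c("xy_at_depth", "xz", "yz", "volume"),
                            spacing = 1, depth_range = c(1, 6), depth_reference = 1,
                            dwell_s = 0.8, n_readings = 3) {
  plane_kind <- match.arg(plane_kind)
  stopifnot(inherits(surface, "contact_surface"), inherits(frame, "coordinate_frame"),
            inherits(bbox, "bounding_box"))
  if (!is.numeric(spacing) || spacing <= 0) {
    stop_sarscan("spacing must be > 0", class = "sarscan_bad_spacing")
  }
  if (plane_kind != "xy_at_depth" && abs(depth_range[1] - depth_reference) > 1e-9) {
    stop_sarscan("depth_range must start at the reference depth (", depth_reference, " cm)",
                 class = "sarscan_bad_depth_range")
  }
  u_vals <- axis_nodes(bbox$xlim, spacing)
  v_vals <- axis_nodes(bbox$ylim, spacing)
  if (plane_kind %in% c("xy_at_depth", "volume") && (length(u_vals) == 0L || length(v_vals) == 0L) ||
      plane_kind == "xz" && length(u_vals) == 0L || plane_kind == "yz" && length(v_vals) == 0L) {
    stop_sarscan("empty plan: spacing ", spacing, " cm exceeds the bounding-box extent",
                 class = "sarscan_empty_plan")
  }
  depths <- if (plane_kind == "xy_at_depth") depth_reference else {
    depth_reference + axis_nodes(c(0, depth_range[2] - depth_reference), spacing)
  }
  if (surface$kind == "cylinder") {
    max_angle <- max(abs(c(u_vals, 0))) / surface$radius
    if (max_angle > pi / 2) {
      stop_sarscan("out of workspace: arc extent exceeds a quarter circle of the contact surface",
                   class = "sarscan_out_of_workspace")
    }
    if (max(depths) > 2 * surface$radius) {
      stop_sarscan("out of workspace: requested depth exceeds the geometric reach of the curved surface",
                   class = "sarscan_out_of_workspace")
    }
  }
  boustro <- function(vals, row_i) if (row_i %% 2L == 0L) rev(vals) else vals
  rows <- switch(plane_kind,
    xy_at_depth = {
      do.call(rbind, lapply(seq_along(v_vals), function(i) {
        cbind(u = boustro(u_vals, i), v = v_vals[i], depth = depth_reference)
      }))
    },
    xz = {
      do.call(rbind, lapply(seq_along(depths), function(i) {
        cbind(u = boustro(u_vals, i), v = 0, depth = depths[i])
      }))
    },
    yz = {
      do.call(rbind, lapply(seq_along(depths), function(i) {
        cbind(u = 0, v = boustro(v_vals, i), depth = depths[i])
      }))
    },
    volume = {
      do.call(rbind, lapply(seq_along(depths), function(k) {
        do.call(rbind, lapply(seq_along(v_vals), function(i) {
          cbind(u = boustro(u_vals, i + k - 1L), v = v_vals[i], depth = depths[k])
        }))
      }))
    })
  p_meas <- surface_point(rows, surface)
  p_robot <- to_robot_frame(p_meas, frame)
  points <- data.frame(
    u = rows[, "u"], v = rows[, "v"], depth = rows[, "depth"],
    x_meas = p_meas[, 1], y_meas = p_meas[, 2], z_meas = p_meas[, 3],
    x_robot = p_robot[, 1], y_robot = p_robot[, 2], z_robot = p_robot[, 3]
  )
  structure(list(
    plane_kind = plane_kind, spacing = spacing, depth_reference = depth_reference,
    depth_range = if (plane_kind == "xy_at_depth") c(depth_reference, depth_reference) else as.numeric(depth_range),
    dwell_s = dwell_s, n_readings = as.integer(n_readings),
    surface = surface, frame = frame, bbox = bbox, points = points
  ), class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("<scan_plan> ", x$plane_kind, ", ", nrow(x$points), " points, spacing ",
      x$spacing, " cm, surface ", x$surface$kind, "\n", sep = "")
  invisible(x)
}

#' Emit a motion program (G-code) for a scan plan
#'
#' The dialect is metric (`G21`) absolute (`G90`): one `G1` move per point in
#' robot coordinates (converted cm to mm), a `G4` dwell for multimetre
#' stabilisation, and a `(READ n=...)` comment marker. The scan runner, not
#' the motion controller, triggers the voltage readings at the markers.
#'
#' @param plan A [build_scan_plan()] result.
#' @return Character vector of G-code lines.
#' @export
emit_gcode <- function(plan) {
  stopifnot(inherits(plan, "scan_plan"))
  pts <- plan$points
  if (nrow(pts) == 0L) stop_sarscan("cannot emit G-code for an empty plan", class = "sarscan_empty_plan")
  body <- vapply(seq_len(nrow(pts)), function(i) {
    paste0(
      "G1 X", fmt17(pts$x_robot[i] * 10), " Y", fmt17(pts$y_robot[i] * 10),
      " Z", fmt17(pts$z_robot[i] * 10), "\n",
      "G4 P", fmt17(plan$dwell_s), "\n",
      "(READ n=", plan$n_readings, ")")
  }, character(1))
  c("G21", "G90", unlist(strsplit(body, "\n", fixed = TRUE)))
}

#' Parse a motion program back into its point sequence
#'
#' @param lines Character vector of G-code lines (as from [emit_gcode()]).
#' @return List with `points` (n x 3 matrix of robot coordinates, cm),
#'   `dwell_s`, `n_readings`.
#' @export
parse_gcode <- function(lines) {
  g1 <- grep("^G1 ", lines, value = TRUE)
  num <- function(axis) as.numeric(sub(paste0(".*", axis, "([-+0-9.eE]+).*"), "\\1", g1)) / 10
  pts <- cbind(x = num("X"), y = num("Y"), z = num("Z"))
  g4 <- grep("^G4 P", lines, value = TRUE)
  rd <- grep("^\\(READ n=", lines, value = TRUE)
  list(points = pts,
       dwell_s = if (length(g4)) as.numeric(sub("^G4 P", "", g4[1])) else NA_real_,
       n_readings = if (length(rd)) as.integer(sub("^\\(READ n=([0-9]+)\\)$", "\\1", rd[1])) else NA_integer_,
       n_read_markers = length(rd))
}

#' Write / read a scan plan as JSON
#'
#' @param plan A `scan_plan`.
#' @param path File path.
#' @return `read_scan_plan` returns a `scan_plan`; `write_scan_plan` the path.
#' @export
write_scan_plan <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  obj <- list(
    schema = "sarscan/plan/1",
    plane_kind = plan$plane_kind, spacing = plan$spacing,
    depth_reference = plan$depth_reference, depth_range = plan$depth_range,
    dwell_s = plan$dwell_s, n_readings = plan$n_readings,
    surface = list(kind = plan$surface$kind,
                   radius = if (is.finite(plan$surface$radius)) plan$surface$radius else NULL,
                   circle_center = plan$surface$circle_center),
    frame = list(origin_in_robot = plan$frame$origin_in_robot, z_sign_flip = plan$frame$z_sign_flip),
    bbox = list(xlim = plan$bbox$xlim, ylim = plan$bbox$ylim, zlim = plan$bbox$zlim),
    points = plan$points
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  })
}

#' @rdname write_scan_plan
#' @export
read_scan_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "sarscan/plan/1")) {
    stop_sarscan("not a sarscan plan file: ", path, class = "sarscan_parse_error")
  }
  surface <- if (identical(obj$surface$kind, "flat")) flat_surface() else
    cylinder_surface(obj$surface$radius, obj$surface$circle_center)
  structure(list(
    plane_kind = obj$plane_kind, spacing = obj$spacing,
    depth_reference = obj$depth_reference, depth_range = obj$depth_range,
    dwell_s = obj$dwell_s, n_readings = as.integer(obj$n_readings),
    surface = surface,
    frame = coordinate_frame(obj$frame$origin_in_robot, obj$frame$z_sign_flip),
    bbox = bounding_box(obj$bbox$xlim, obj$bbox$ylim, obj$bbox$zlim),
    points = as.data.frame(obj$points)
  ), class = "scan_plan")
}
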