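#' QA studies: spatial resolution, repeatability, applicator characterization
#'
#' These functions compose the full pipeline -- scan plan, (virtual) scan,
#' per-session calibration, normalisation, interpolation, metrics -- into the
#' three reproducible studies that qualify a routine QA protocol: how coarse
#' the measurement grid may be, how repeatable the metrics are across
#' sessions, and how EFS/EPD respond to curvature and bolus thickness.
#'
#' @name sarscan-workflows
NULL

default_bbox <- function() bounding_box(c(-16, 16), c(-12, 12), c(0, 6))

#' Run one full measurement session on the virtual setup
#'
#' Applies the session seed once, draws a single positioning offset, runs a
#' calibration sweep and fit, then runs and analyses the requested plane
#' scans, mirroring one measurement day of the physical procedure.
#'
#' @param model An [applicator_model()].
#' @param sensor A [diode_sensor()].
#' @param plans Named list of `scan_plan`s (names among `xy`, `xz`, `yz`,
#'   `volume`).
#' @param noise A [session_noise()]; its seed defines the session.
#' @param power Generator power, W.
#' @param calibration_point Surface coordinates of the calibration position.
#' @return List with per-plane analysed records (`records`), the fitted
#'   `curve`, the drawn `offset`, and `metrics` (`efs` from xy, `epd_xz`,
#'   `epd_yz`).
#' @export
run_qa_session <- function(model, sensor, plans, noise = session_noise(0, 0),
                           power = 30, calibration_point = c(0, 0, 1)) {
  stopifnot(is.list(plans), length(plans) > 0L)
  noise_seed(noise)
  offset <- draw_session_offset(noise)
  stream <- noise; stream$seed <- NULL  # continue the session RNG stream
  sweep <- run_calibration_sweep(model, sensor, stream, point = calibration_point,
                                 offset = offset)
  curve <- fit_calibration(sweep, session_id = noise$seed %||% NA)
  records <- list()
  metrics <- list()
  for (nm in names(plans)) {
    rec <- run_virtual_scan(plans[[nm]], model, sensor, stream, power, offset = offset)
    rec <- voltages_to_power(rec, curve, check_session = FALSE)
    rec <- normalize_relative_sar(rec, depth_reference = plans[[nm]]$depth_reference)
    records[[nm]] <- rec
    if (nm == "xy") {
      grid <- interpolate_plane(rec, axes = c("u", "v"))
      metrics$efs <- compute_efs(grid)
      metrics$xy_grid <- grid
    } else if (nm == "xz") {
      grid <- interpolate_plane(rec, axes = c("u", "depth"))
      metrics$epd_xz <- compute_epd_from_plane(grid)
    } else if (nm == "yz") {
      grid <- interpolate_plane(rec, axes = c("v", "depth"))
      metrics$epd_yz <- compute_epd_from_plane(grid)
    }
  }
  list(records = records, curve = curve, offset = offset, metrics = metrics)
}

#' Spatial-resolution study
#'
#' Subsets a fine normalised xy-plane scan (no interpolation: points on the
#' coarse grid are kept) to each coarser spacing, interpolates every point
#' set to the fine analysis grid independently, and compares the resulting
#' EFS values against the full-resolution reference.
#'
#' @param fine_record Normalised xy-plane `scan_record` at the reference
#'   spacing (e.g. 0.25 cm), phase-anchored at the origin.
#' @param spacings Coarse spacings to evaluate, cm (default `c(1, 2, 4)`).
#' @param source_spacing Spacing of `fine_record`; from metadata if missing.
#' @param isoline_levels Levels for the per-spacing isoline sets.
#' @return Object of class `resolution_study`: a `table` data frame
#'   (spacing, n_points, efs_x, efs_y, relative differences in percent vs
#'   the reference row) plus per-spacing isoline sets and
#'   `max_rel_diff_pct`.
#' @export
resolution_study <- function(fine_record, spacings = c(1, 2, 4),
                             source_spacing = NULL,
                             isoline_levels = c(50, 70, 80, 90, 98)) {
  stopifnot("sar" %in% names(fine_record))
  meta <- attr(fine_record, "metadata")
  source_spacing <- source_spacing %||% meta$spacing_cm
  all_spacings <- c(source_spacing, setdiff(spacings, source_spacing))
  rows <- list(); isolines <- list()
  for (sp in all_spacings) {
    sub <- resample_plane(fine_record, sp, source_spacing)
    grid <- interpolate_plane(sub, axes = c("u", "v"))
    efs <- compute_efs(grid)
    isolines[[as.character(sp)]] <- extract_isolines(grid, isoline_levels)
    rows[[as.character(sp)]] <- data.frame(
      spacing = sp, n_points = nrow(sub),
      efs_x = efs$efs_x, efs_y = efs$efs_y,
      dx = efs$dx, dy = efs$dy, area = efs$area)
  }
  tab <- do.call(rbind, rows)
  ref <- tab[1, ]
  tab$rel_diff_x_pct <- (tab$efs_x - ref$efs_x) / ref$efs_x * 100
  tab$rel_diff_y_pct <- (tab$efs_y - ref$efs_y) / ref$efs_y * 100
  coarse <- tab$spacing != source_spacing
  structure(list(
    table = tab, isolines = isolines, reference_spacing = source_spacing,
    max_rel_diff_pct = if (any(coarse))
      max(abs(c(tab$rel_diff_x_pct[coarse], tab$rel_diff_y_pct[coarse]))) else 0
  ), class = "resolution_study")
}

#' @export
print.resolution_study <- function(x, ...) {
  cat("<resolution_study> reference", x$reference_spacing, "cm; max |EFS difference| =",
      sprintf("%.2f%%", x$max_rel_diff_pct), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Repeatability study over independent sessions
#'
#' Simulates `n_sessions` fully independent measurement days: each session
#' draws its own positioning offset, calibrates the sensor afresh, scans the
#' xy-, xz- and yz-planes, and extracts the QA metrics. Reported are the
#' per-metric mean, sample standard deviation (n - 1 denominator) and SD as
#' a percent of the absolute mean.
#'
#' @param model An [applicator_model()] (or preset name).
#' @param sensor A [diode_sensor()].
#' @param n_sessions Number of sessions (>= 2).
#' @param seeds One seed per session (default `1:n_sessions`).
#' @param position_sd,reading_sd Session noise parameters (cm, fraction).
#' @param power Generator power, W.
#' @param bbox Scan [bounding_box()].
#' @param spacing Grid spacing, cm.
#' @param surface Contact surface (default flat).
#' @param frame Coordinate frame.
#' @return Object of class `repeatability_result`: per-session metric table
#'   (`sessions`), summary `table` (metric, mean, sd, sd_pct), and notes on
#'   any censored-EPD sessions (excluded from the EPD summary).
#' @export
repeatability_study <- function(model, sensor = diode_sensor(), n_sessions = 8,
                                seeds = seq_len(n_sessions),
                                position_sd = 0.5, reading_sd = 0.004, power = 30,
                                bbox = default_bbox(), spacing = 1,
                                surface = flat_surface(), frame = coordinate_frame()) {
  if (is.character(model)) model <- scenario_preset(model)
  stopifnot(n_sessions >= 2, length(seeds) == n_sessions)
  plans <- list(
    xy = build_scan_plan(surface, frame, bbox, "xy_at_depth", spacing),
    xz = build_scan_plan(surface, frame, bbox, "xz", spacing, depth_range = c(1, bbox$zlim[2])),
    yz = build_scan_plan(surface, frame, bbox, "yz", spacing, depth_range = c(1, bbox$zlim[2]))
  )
  rows <- vector("list", n_sessions)
  notes <- character(0)
  for (i in seq_len(n_sessions)) {
    noise <- session_noise(position_sd, reading_sd, seed = seeds[i])
    ses <- run_qa_session(model, sensor, plans, noise, power)
    m <- ses$metrics
    if (m$epd_xz$censored || m$epd_yz$censored) {
      notes <- c(notes, paste0("session seed ", seeds[i],
                               ": censored EPD, excluded from EPD summary"))
    }
    rows[[i]] <- data.frame(
      session = i, seed = seeds[i],
      efs_x = m$efs$efs_x, efs_y = m$efs$efs_y,
      dx = m$efs$dx, dy = m$efs$dy,
      epd_xz = m$epd_xz$epd, epd_yz = m$epd_yz$epd,
      offset_u = ses$offset[1], offset_v = ses$offset[2])
  }
  sessions <- do.call(rbind, rows)
  summ <- function(x, pct = TRUE) {
    x <- x[is.finite(x)]
    c(mean = mean(x), sd = sd(x),
      sd_pct = if (pct) sd(x) / abs(mean(x)) * 100 else NA_real_)
  }
  tab <- rbind(
    efs_x = summ(sessions$efs_x),
    efs_y = summ(sessions$efs_y),
    dx = summ(sessions$dx, pct = FALSE),
    dy = summ(sessions$dy, pct = FALSE),
    epd_xz = summ(sessions$epd_xz),
    epd_yz = summ(sessions$epd_yz))
  tab <- data.frame(metric = rownames(tab), tab, row.names = NULL)
  structure(list(sessions = sessions, table = tab, notes = notes,
                 n_sessions = n_sessions),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("<repeatability_result>", x$n_sessions, "sessions\n")
  tab <- x$table
  tab$mean <- sprintf("%.3f", tab$mean)
  tab$sd <- sprintf("%.3f", tab$sd)
  tab$sd_pct <- ifelse(is.na(x$table$sd_pct), "-", sprintf("%.1f%%", x$table$sd_pct))
  print(tab, row.names = FALSE)
  if (length(x$notes)) cat(paste0("note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Applicator characterization across setup conditions
#'
#' Runs the xy- and xz-plane pipeline for each scenario (applicator x
#' curvature x bolus thickness), reporting EFS, centre shifts, EPD and
#' isoline component counts, plus cross-scenario deltas (EPD and EFS versus
#' curvature within each applicator/bolus group). For each scenario the
#' report checks whether the xy-plane region above `axis_gate` percent
#' intersects the central x axis (v = 0 line): if not, the central-plane EPD
#' is flagged and an extra scan at the maximum-SAR position is demanded.
#'
#' @param scenarios Character vector of preset names (see
#'   [scenario_preset()]) or a named list of [applicator_model()]s.
#' @param sensor A [diode_sensor()].
#' @param power Generator power, W.
#' @param noise A [session_noise()] (default: noiseless).
#' @param bbox Scan [bounding_box()].
#' @param spacing Grid spacing, cm.
#' @param axis_gate Percent level the central axis must cross for the
#'   central-plane EPD to be accepted (default 80; configurable 80-90).
#' @param frame Coordinate frame.
#' @param calibration_point Surface coordinates of the calibration position
#'   (must be a high-SAR position so the sweep covers the scan voltages).
#' @return Object of class `characterization_report`: per-scenario metric
#'   list, a summary `table`, and `deltas` across curvature.
#' @export
characterize_applicator <- function(scenarios, sensor = diode_sensor(), power = 30,
                                    noise = session_noise(0, 0),
                                    bbox = default_bbox(), spacing = 1,
                                    axis_gate = 80, frame = coordinate_frame(),
                                    calibration_point = c(0, 0, 1)) {
  stopifnot(axis_gate >= 50, axis_gate <= 98)
  models <- if (is.character(scenarios)) {
    setNames(lapply(scenarios, scenario_preset), scenarios)
  } else scenarios
  stopifnot(is.list(models), length(models) > 0L)
  out <- list(); rows <- list()
  for (nm in names(models)) {
    model <- models[[nm]]
    surface <- if (is.finite(model$curvature_radius))
      cylinder_surface(model$curvature_radius) else flat_surface()
    plans <- list(
      xy = build_scan_plan(surface, frame, bbox, "xy_at_depth", spacing),
      xz = build_scan_plan(surface, frame, bbox, "xz", spacing, depth_range = c(1, bbox$zlim[2]))
    )
    ses <- run_qa_session(model, sensor, plans, noise, power,
                          calibration_point = calibration_point)
    grid <- ses$metrics$xy_grid
    iso <- extract_isolines(grid)
    # does the >= axis_gate region cross the x axis (v = 0)?
    j0 <- which(abs(grid$a2) <= grid$spacing / 2)
    gate_ok <- length(j0) > 0 && any(grid$values[, j0] >= axis_gate & !grid$mask[, j0])
    efs <- ses$metrics$efs
    epd <- ses$metrics$epd_xz
    out[[nm]] <- list(
      scenario = nm, model = model, efs = efs, epd = epd, isolines = iso,
      axis_gate = axis_gate, axis_gate_ok = gate_ok,
      needs_max_sar_scan = !gate_ok,
      calibration_session = ses$curve$session_id)
    rows[[nm]] <- data.frame(
      scenario = nm, applicator = model$name,
      curvature_cm = if (is.finite(model$curvature_radius)) model$curvature_radius else Inf,
      bolus_cm = model$bolus_cm,
      efs_x = efs$efs_x, efs_y = efs$efs_y, dx = efs$dx, dy = efs$dy,
      epd = epd$epd, epd_censored = epd$censored,
      n50_components = iso$sets[["50"]]$n_components,
      axis_gate_ok = gate_ok)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  # EPD/EFS deltas versus the flat setup within applicator x bolus groups
  deltas <- list()
  key <- paste(sub("-.*", "", tab$scenario), tab$bolus_cm)
  for (k in unique(key)) {
    g <- tab[key == k, , drop = FALSE]
    flat <- g[!is.finite(g$curvature_cm), , drop = FALSE]
    if (nrow(flat) == 1L && nrow(g) > 1L) {
      g$epd_delta_vs_flat <- g$epd - flat$epd
      g$efs_x_delta_vs_flat <- g$efs_x - flat$efs_x
      deltas[[k]] <- g[, c("scenario", "curvature_cm", "epd_delta_vs_flat", "efs_x_delta_vs_flat")]
    }
  }
  structure(list(scenarios = out, table = tab, deltas = deltas),
            class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("<characterization_report>", nrow(x$table), "scenario(s)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
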