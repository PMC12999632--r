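#' Relative-SAR grids, isolines and QA metrics
#'
#' Scanned planes are interpolated to a fine regular grid (0.1 x 0.1 cm by
#' default), from which the QA metrics are read off: the effective field
#' size (EFS) from the extent of the 50% region at the reference depth, the
#' centre shifts from the midpoint of the 50% extremes, and the effective
#' penetration depth (EPD) from the depth at which SAR falls to half its
#' value at the 1 cm reference depth.
#'
#' @name sarscan-metrics
NULL

round_key <- function(x) round(x, 6)

#' Interpolate a scanned plane to a fine regular grid
#'
#' Measurement points produced by this pipeline lie on a phase-anchored
#' raster, so piecewise-linear interpolation reduces to exact bilinear
#' interpolation on the measurement rectangles; measurement points are
#' reproduced exactly at their own locations. Non-raster point clouds are
#' rejected (no scattered-data triangulation is performed).
#'
#' @param record Data frame of measured points with the two axis columns and
#'   a value column (typically a normalised `scan_record`).
#' @param axes Character vector of the two axis column names, e.g.
#'   `c("u", "v")` for an xy-plane or `c("u", "depth")` for an xz-plane.
#' @param value Name of the value column (default `"sar"`).
#' @param spacing_out Output grid spacing in cm (default 0.1), phase-anchored
#'   at the measurement origin.
#' @return Object of class `relative_sar_grid`: axis vectors `a1`, `a2`,
#'   a values matrix, a logical `mask` (cells outside the measured region),
#'   axis names and provenance.
#' @export
interpolate_plane <- function(record, axes = c("u", "v"), value = "sar",
                              spacing_out = 0.1) {
  stopifnot(length(axes) == 2L, all(axes %in% names(record)), value %in% names(record))
  x <- record[[axes[1]]]; y <- record[[axes[2]]]; z <- record[[value]]
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  xa <- sort(unique(round_key(x)))
  ya <- sort(unique(round_key(y)))
  if (length(xa) < 2L || length(ya) < 2L) {
    stop_sarscan("cannot interpolate a collinear point cloud (need at least a 2 x 2 raster)",
                 class = "sarscan_collinear_points")
  }
  ix <- match(round_key(x), xa); iy <- match(round_key(y), ya)
  Z <- matrix(NA_real_, length(xa), length(ya))
  Z[cbind(ix, iy)] <- z
  if (anyNA(Z)) {
    stop_sarscan("measured points do not form a complete raster grid; ",
                 "scattered-data interpolation is not supported",
                 class = "sarscan_not_raster")
  }
  xo <- axis_nodes(range(xa), spacing_out)
  yo <- axis_nodes(range(ya), spacing_out)
  V <- bilinear_interp(xa, ya, Z, xo, yo)
  meta <- attr(record, "metadata")
  structure(list(
    a1 = xo, a2 = yo, values = V,
    mask = matrix(FALSE, length(xo), length(yo)),
    axes = axes, spacing = spacing_out,
    source = list(a1 = xa, a2 = ya, values = Z),
    provenance = list(plane_kind = meta$plane_kind %||% NA,
                      applicator = meta$applicator %||% NA,
                      session_id = meta$session_id %||% NA)
  ), class = "relative_sar_grid")
}

#' @export
print.relative_sar_grid <- function(x, ...) {
  cat("<relative_sar_grid> ", paste(x$axes, collapse = " x "), ", ",
      length(x$a1), " x ", length(x$a2), " cells at ", x$spacing, " cm\n", sep = "")
  invisible(x)
}

#' Extract isolines and level regions from a relative-SAR grid
#'
#' Contours come from marching squares ([grDevices::contourLines()]); the
#' per-level region is the set of unmasked cells at or above the level, with
#' its connected components counted (4-connectivity). Regions are nested:
#' each higher level's region is a subset of every lower one.
#'
#' @param grid A [interpolate_plane()] result.
#' @param levels Percent levels (default `c(50, 70, 80, 90, 98)`).
#' @return Object of class `isoline_set`: per level, `polylines` (list of
#'   `x`/`y` paths), `n_components`, `n_cells` and `area` (cm^2). Levels
#'   above the grid maximum yield empty entries.
#' @export
extract_isolines <- function(grid, levels = c(50, 70, 80, 90, 98)) {
  stopifnot(inherits(grid, "relative_sar_grid"))
  vals <- grid$values
  vals[grid$mask] <- NA_real_
  per_level <- lapply(levels, function(lev) {
    region <- !is.na(vals) & vals >= lev
    comps <- label_components(region)
    polys <- if (any(region) && lev < max(vals, na.rm = TRUE)) {
      grDevices::contourLines(grid$a1, grid$a2, vals, levels = lev)
    } else list()
    list(level = lev, polylines = polys, n_components = comps$n,
         n_cells = sum(region), area = sum(region) * grid$spacing^2)
  })
  names(per_level) <- as.character(levels)
  structure(list(levels = levels, sets = per_level, spacing = grid$spacing),
            class = "isoline_set")
}

#' Effective field size and centre shifts
#'
#' EFS along each axis is the difference between the maximum and minimum
#' coordinate of the 50% contour (all connected components pooled); the
#' centre shifts are the midpoints of those extremes relative to the
#' visually aligned origin. Extremes are taken over the marching-squares
#' contour vertices together with the centres of the cells at or above the
#' level, which resolves the crossing to sub-cell precision; the area is the
#' cell count times the cell area.
#'
#' @param grid A [interpolate_plane()] result for an xy-plane.
#' @param level Threshold in percent (default 50).
#' @return Object of class `qa_metrics`: `efs_x`, `efs_y`, `dx`, `dy`,
#'   `area`, `n_components`, `level`. A warning is raised when the region
#'   touches the grid boundary (scan bounding box too small).
#' @export
compute_efs <- function(grid, level = 50) {
  stopifnot(inherits(grid, "relative_sar_grid"))
  vals <- grid$values
  region <- !grid$mask & is.finite(vals) & vals >= level
  if (!any(region)) {
    stop_sarscan("the ", level, "% region is empty", class = "sarscan_empty_region")
  }
  idx <- which(region, arr.ind = TRUE)
  uu <- grid$a1[idx[, 1]]; vv <- grid$a2[idx[, 2]]
  if (min(idx[, 1]) == 1L || max(idx[, 1]) == length(grid$a1) ||
      min(idx[, 2]) == 1L || max(idx[, 2]) == length(grid$a2)) {
    warning("the ", level, "% region touches the measured boundary; ",
            "EFS may be truncated (enlarge the scan bounding box)", call. = FALSE)
  }
  cl_vals <- vals; cl_vals[grid$mask] <- NA_real_
  if (level < max(cl_vals, na.rm = TRUE)) {
    polys <- grDevices::contourLines(grid$a1, grid$a2, cl_vals, levels = level)
    for (p in polys) {
      uu <- c(uu, p$x); vv <- c(vv, p$y)
    }
  }
  comps <- label_components(region)
  structure(list(
    efs_x = max(uu) - min(uu),
    efs_y = max(vv) - min(vv),
    dx = (max(uu) + min(uu)) / 2,
    dy = (max(vv) + min(vv)) / 2,
    area = nrow(idx) * grid$spacing^2,
    n_components = comps$n,
    level = level
  ), class = "qa_metrics")
}

#' @export
print.qa_metrics <- function(x, ...) {
  cat(sprintf("<qa_metrics> EFS %.2f x %.2f cm, centre shift (%+.2f, %+.2f) cm, area %.1f cm^2, %d component(s) at %g%%\n",
              x$efs_x, x$efs_y, x$dx, x$dy, x$area, x$n_components, x$level))
  invisible(x)
}

# First downward crossing of `target` along (depths, values), starting from
# the reference depth, with linear interpolation between samples.
depth_crossing <- function(depths, values, target, depth_reference = 1) {
  keep <- depths >= depth_reference - 1e-9
  d <- depths[keep]; v <- values[keep]
  o <- order(d); d <- d[o]; v <- v[o]
  j <- which(v <= target)[1]
  if (is.na(j)) return(NA_real_)
  if (j == 1L) return(d[1])
  d[j - 1L] + (d[j] - d[j - 1L]) * (v[j - 1L] - target) / (v[j - 1L] - v[j])
}

#' Effective penetration depth from a depth plane
#'
#' Locates the lateral position of the plane's maximum SAR (ties broken
#' towards the smallest absolute lateral coordinate); along that column the
#' EPD is the additional depth, beyond the 1 cm reference, at which the SAR
#' first falls to 50% of its value at the reference depth, with linear
#' interpolation between depth samples.
#'
#' @param grid A [interpolate_plane()] result for an xz- or yz-plane
#'   (axes `c("u", "depth")` or `c("v", "depth")`).
#' @param depth_reference Reference depth, cm (default 1).
#' @param min_additional_depth Minimum additional measured depth required
#'   (default 4 cm).
#' @param convention `"additional"` (default: depth beyond the reference
#'   plane) or `"from_interface"` (depth below the bolus--phantom interface).
#' @return Object of class `epd_result`: `epd` (cm, `NA` when censored),
#'   `censored`, `column` (lateral coordinate used), `reference_value`,
#'   `convention`.
#' @export
compute_epd_from_plane <- function(grid, depth_reference = 1,
                                   min_additional_depth = 4,
                                   convention = c("additional", "from_interface")) {
  stopifnot(inherits(grid, "relative_sar_grid"))
  convention <- match.arg(convention)
  if (!identical(grid$axes[2], "depth")) {
    stop_sarscan("compute_epd_from_plane expects a grid with a depth axis (xz or yz plane)",
                 class = "sarscan_bad_plane")
  }
  depths <- grid$a2
  if (min(abs(depths - depth_reference)) > 1e-6) {
    stop_sarscan("grid does not include the ", depth_reference, " cm reference depth",
                 class = "sarscan_no_reference")
  }
  if (max(depths) < depth_reference + min_additional_depth - 1e-9) {
    stop_sarscan("plane must extend at least ", min_additional_depth,
                 " cm beyond the reference depth", class = "sarscan_too_shallow")
  }
  vals <- grid$values
  vals[grid$mask] <- NA_real_
  mx <- max(vals, na.rm = TRUE)
  cand <- which(vals == mx, arr.ind = TRUE)
  lat <- abs(grid$a1[cand[, 1]])
  i_col <- cand[order(lat, grid$a1[cand[, 1]])[1], 1]
  col_vals <- vals[i_col, ]
  ref <- col_vals[which.min(abs(depths - depth_reference))]
  d50 <- depth_crossing(depths, col_vals, ref / 2, depth_reference)
  censored <- is.na(d50)
  if (censored) {
    warning("no 50% crossing within the measured depth; EPD is censored (> ",
            max(depths) - depth_reference, " cm additional depth)", call. = FALSE)
  }
  epd <- if (censored) NA_real_ else if (convention == "additional") d50 - depth_reference else d50
  structure(list(epd = epd, censored = censored, column = grid$a1[i_col],
                 reference_value = ref, convention = convention,
                 max_depth = max(depths)),
            class = "epd_result")
}

#' @export
print.epd_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<epd_result> censored (> %.2f cm %s), column at %.2f cm\n",
                x$max_depth, x$convention, x$column))
  } else {
    cat(sprintf("<epd_result> EPD = %.3f cm (%s depth), column at %.2f cm\n",
                x$epd, x$convention, x$column))
  }
  invisible(x)
}

#' Assemble a SAR volume from a normalised volume scan
#'
#' @param record Normalised volume `scan_record` (columns `u`, `v`, `depth`,
#'   `sar`).
#' @param depth_reference Reference depth, cm.
#' @return Object of class `sar_volume`: axis vectors `u`, `v`, `depth` and
#'   a 3-D values array (percent).
#' @export
build_sar_volume <- function(record, depth_reference = 1) {
  stopifnot(all(c("u", "v", "depth", "sar") %in% names(record)))
  u <- sort(unique(round_key(record$u)))
  v <- sort(unique(round_key(record$v)))
  d <- sort(unique(round_key(record$depth)))
  if (abs(d[1] - depth_reference) > 1e-6) {
    stop_sarscan("volume depth axis must start at the ", depth_reference,
                 " cm reference depth", class = "sarscan_no_reference")
  }
  A <- array(NA_real_, c(length(u), length(v), length(d)))
  A[cbind(match(round_key(record$u), u), match(round_key(record$v), v),
          match(round_key(record$depth), d))] <- record$sar
  if (anyNA(A)) {
    stop_sarscan("volume scan does not form a complete (u, v, depth) raster",
                 class = "sarscan_not_raster")
  }
  structure(list(u = u, v = v, depth = d, values = A,
                 depth_reference = depth_reference),
            class = "sar_volume")
}

#' EPD variation map across the aperture
#'
#' For every `(u, v)` column of the volume, the EPD is the additional depth
#' at which the SAR falls to 50% of that column's own value at the reference
#' depth (linear interpolation between depth samples). The map reports the
#' relative difference to the EPD at the position of the maximum SAR on the
#' reference layer,
#' \deqn{\Delta EPD(x,y) = \frac{EPD(x,y) - EPD(\mathrm{max\,SAR})}{EPD(\mathrm{max\,SAR})} \times 100\%,}
#' the region where the absolute difference is at most `threshold` percent,
#' and whether the central x and y axes pass through that region (in which
#' case the central xz/yz planes give a good EPD estimate).
#'
#' @param volume A [build_sar_volume()] result.
#' @param threshold Region threshold in percent (default 5).
#' @return Object of class `delta_epd_map`: matrices `epd` and `delta`
#'   (percent), `epd_max_sar`, `max_sar_uv`, logical `region` and `censored`
#'   matrices, axis-crossing flags `x_axis_in_region` (v = 0 line) and
#'   `y_axis_in_region` (u = 0 line), and the count of censored columns.
#' @export
compute_delta_epd <- function(volume, threshold = 5) {
  stopifnot(inherits(volume, "sar_volume"))
  u <- volume$u; v <- volume$v; d <- volume$depth
  ref_layer <- volume$values[, , 1]
  mx <- max(ref_layer)
  cand <- which(ref_layer == mx, arr.ind = TRUE)
  # tie-break: smallest distance to origin, then lexicographic (u, v)
  du <- u[cand[, 1]]; dv <- v[cand[, 2]]
  pick <- order(du^2 + dv^2, du, dv)[1]
  max_uv <- c(u = du[pick], v = dv[pick])
  i_max <- cand[pick, 1]; j_max <- cand[pick, 2]
  nu <- length(u); nv <- length(v)
  epd <- matrix(NA_real_, nu, nv)
  for (i in seq_len(nu)) {
    for (j in seq_len(nv)) {
      col_vals <- volume$values[i, j, ]
      d50 <- depth_crossing(d, col_vals, col_vals[1] / 2, volume$depth_reference)
      epd[i, j] <- if (is.na(d50)) NA_real_ else d50 - volume$depth_reference
    }
  }
  censored <- is.na(epd)
  epd_max <- epd[i_max, j_max]
  if (is.na(epd_max)) {
    stop_sarscan("EPD is censored at the maximum-SAR column: the volume is too shallow",
                 class = "sarscan_too_shallow")
  }
  delta <- (epd - epd_max) / epd_max * 100
  delta[i_max, j_max] <- 0
  region <- !censored & abs(delta) <= threshold
  su <- if (nu > 1) min(diff(u)) else 1
  sv <- if (nv > 1) min(diff(v)) else 1
  on_x_axis <- abs(v) <= sv / 2   # columns on the v = 0 line (x axis)
  on_y_axis <- abs(u) <= su / 2   # columns on the u = 0 line (y axis)
  structure(list(
    u = u, v = v, epd = epd, delta = delta,
    epd_max_sar = epd_max, max_sar_uv = max_uv,
    region = region, censored = censored, n_censored = sum(censored),
    threshold = threshold,
    x_axis_in_region = any(region[, on_x_axis]),
    y_axis_in_region = any(region[on_y_axis, ])
  ), class = "delta_epd_map")
}

#' Absolute EPD difference at a relative-difference boundary
#'
#' Inverts the relative EPD difference: at the `pct`% boundary of the
#' variation map, columns differ from `epd_max_sar` by
#' `pct / 100 * epd_max_sar` centimetres.
#'
#' @param pct Relative difference boundary in percent.
#' @param epd_max_sar EPD at the maximum-SAR position, cm.
#' @return Absolute EPD difference in cm.
#' @export
delta_epd_threshold <- function(pct, epd_max_sar) {
  stopifnot(pct >= 0, epd_max_sar > 0)
  pct / 100 * epd_max_sar
}

#' Subset a fine scan to a coarser, phase-commensurate resolution
#'
#' No interpolation is performed: the coarse plane keeps exactly those
#' measured points whose lateral coordinates are integer multiples of the
#' target spacing (both grids are anchored at the measurement origin, so the
#' coarse grid is a strict subset of the fine one).
#'
#' @param record Scan record (or data frame with `u`, `v` columns).
#' @param target_spacing Target spacing, cm; must be an integer multiple of
#'   the source spacing.
#' @param source_spacing Source spacing, cm; taken from the record metadata
#'   when missing.
#' @return The subset record, metadata updated to the target spacing.
#' @export
resample_plane <- function(record, target_spacing, source_spacing = NULL) {
  meta <- attr(record, "metadata")
  source_spacing <- source_spacing %||% meta$spacing_cm
  if (is.null(source_spacing)) {
    stop_sarscan("source spacing unknown: supply source_spacing", class = "sarscan_bad_spacing")
  }
  ratio <- target_spacing / source_spacing
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1 - 1e-9) {
    stop_sarscan("target spacing (", target_spacing,
                 ") must be an integer multiple of the source spacing (",
                 source_spacing, ")", class = "sarscan_incommensurate")
  }
  on_grid <- function(x) abs(x / target_spacing - round(x / target_spacing)) < 1e-6
  keep <- on_grid(record$u) & on_grid(record$v)
  out <- record[keep, , drop = FALSE]
  if (!is.null(meta)) {
    meta$spacing_cm <- target_spacing
    attr(out, "metadata") <- meta
  }
  class(out) <- class(record)
  out
}
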