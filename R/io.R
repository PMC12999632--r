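#' File formats
#'
#' Scan records travel as a CSV of points (comma separated, UTF-8, `.`
#' decimal, mandatory header) plus a JSON metadata sidecar at
#' `<path>.json`; units are fixed (cm, V, W) and asserted in the sidecar.
#' Calibration curves and reports are JSON; run configurations are YAML.
#' All writes are atomic (temp file + rename).
#'
#' @name sarscan-io
NULL

scan_columns <- c("u", "v", "depth", "x_meas", "y_meas", "z_meas",
                  "x_robot", "y_robot", "z_robot", "v1", "v2", "v3", "v_mean")

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a scan record (CSV + JSON metadata sidecar)
#'
#' @param record A `scan_record` (see [run_virtual_scan()]).
#' @param path CSV file path; the sidecar goes to `<path>.json`.
#' @return `read_scan` returns the `scan_record`; `write_scan` the path.
#' @export
write_scan <- function(record, path) {
  stopifnot(all(scan_columns %in% names(record)))
  meta <- attr(record, "metadata") %||% list(schema = "sarscan/scan/1")
  meta$units <- list(length = "cm", voltage = "V", power = "W")
  atomic_write(path, function(tmp) {
    write.csv(as.data.frame(record)[scan_columns], tmp, row.names = FALSE)
  })
  atomic_write(sidecar_path(path), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop_sarscan("scan file not found: ", path, class = "sarscan_parse_error")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop_sarscan("missing metadata sidecar: ", sp, class = "sarscan_parse_error")
  }
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(scan_columns, names(df))
  if (length(missing)) {
    stop_sarscan("scan CSV is missing column(s): ", paste(missing, collapse = ", "),
                 class = "sarscan_parse_error")
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta$units) && !identical(meta$units$length, "cm")) {
    stop_sarscan("unit mismatch in sidecar: expected lengths in cm, got ",
                 meta$units$length, class = "sarscan_parse_error")
  }
  structure(df, metadata = meta, class = c("scan_record", "data.frame"))
}

#' Write / read a calibration curve (JSON)
#'
#' @param curve A [fit_calibration()] result.
#' @param path File path.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(list(
      schema = "sarscan/calibration/1",
      A = curve$A, B = curve$B, C = curve$C,
      r_squared = curve$r_squared, v_range = curve$v_range,
      session_id = curve$session_id
    ), tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_sarscan("cannot parse calibration file ", path, ": ",
                                 conditionMessage(e), class = "sarscan_parse_error")
                  })
  if (!identical(obj$schema, "sarscan/calibration/1")) {
    stop_sarscan("not a sarscan calibration file: ", path, class = "sarscan_parse_error")
  }
  structure(list(A = obj$A, B = obj$B, C = obj$C, r_squared = obj$r_squared,
                 v_range = as.numeric(obj$v_range), session_id = obj$session_id),
            class = "calibration_curve")
}

#' Write a calibration sweep / read one from CSV
#'
#' @param sweep Data frame with `power_W`, `v_out`.
#' @param path CSV path.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(all(c("power_W", "v_out") %in% names(sweep)))
  atomic_write(path, function(tmp) write.csv(sweep[c("power_W", "v_out")], tmp, row.names = FALSE))
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(c("power_W", "v_out"), names(df))
  if (length(missing)) {
    stop_sarscan("sweep CSV is missing column(s): ", paste(missing, collapse = ", "),
                 class = "sarscan_parse_error")
  }
  df
}

run_config_schema <- c("scenario", "planes", "spacing_cm", "power_W", "seed",
                       "seeds", "epd_convention", "axis_gate_pct", "bbox",
                       "out_dir", "schema")

#' Read a run configuration (YAML)
#'
#' Validated against a fixed key set; unknown keys are rejected so typos
#' cannot silently change a QA run.
#'
#' @param path YAML file path.
#' @return Named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_sarscan("run config must be a YAML mapping", class = "sarscan_parse_error")
  unknown <- setdiff(names(cfg), run_config_schema)
  if (length(unknown)) {
    stop_sarscan("unknown run-config key(s): ", paste(unknown, collapse = ", "),
                 class = "sarscan_parse_error")
  }
  defaults <- list(planes = c("xy", "xz"), spacing_cm = 1, power_W = 30, seed = 1,
                   epd_convention = "additional", axis_gate_pct = 80)
  modifyList(defaults, cfg)
}

#' Write a QA report (JSON + Markdown table)
#'
#' @param result A `repeatability_result`, `resolution_study` or
#'   `characterization_report`.
#' @param json_path,md_path Output paths (`NULL` to skip one of them).
#' @export
write_report <- function(result, json_path = NULL, md_path = NULL) {
  tab <- result$table
  if (!is.null(json_path)) {
    payload <- list(schema = "sarscan/report/1",
                    kind = class(result)[1],
                    table = tab,
                    notes = result$notes %||% character(0))
    atomic_write(json_path, function(tmp) {
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
    })
  }
  if (!is.null(md_path)) {
    fmt_cell <- function(x) {
      if (is.numeric(x)) ifelse(is.finite(x), sprintf("%.3g", x), "-") else as.character(x)
    }
    cells <- vapply(tab, fmt_cell, character(nrow(tab)))
    cells <- matrix(cells, nrow = nrow(tab))
    lines <- c(
      paste0("| ", paste(names(tab), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
      apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
    atomic_write(md_path, function(tmp) writeLines(lines, tmp))
  }
  invisible(result)
}
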