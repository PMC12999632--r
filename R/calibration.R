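#' Diode-sensor calibration and voltage-to-power conversion
#'
#' SAR is proportional to the squared E-field (`SAR = sigma |E|^2 / (2 rho)`),
#' so for a fixed probe position the equivalent power at the probe is
#' proportional to the generated power. The diode response is calibrated by
#' sweeping the generator power at a fixed high-SAR position and fitting
#' `P = A V^2 + B V + C`. Applying the fitted quadratic to scan voltages
#' yields power-proportional values, which become relative SAR (percent)
#' after normalisation to the maximum at the reference depth.
#'
#' @name sarscan-calibration
NULL

#' Fit the quadratic voltage-to-power calibration
#'
#' The model `P = A V^2 + B V + C` is linear in its coefficients, so the
#' "nonlinear least squares" fit reduces to ordinary least squares.
#'
#' @param sweep Data frame with columns `power_W` and `v_out` (as from
#'   [run_calibration_sweep()] or a sweep CSV).
#' @param session_id Optional identifier of the measurement session; scans
#'   are expected to be analysed with the calibration of their own session.
#' @return Object of class `calibration_curve`: coefficients `A`, `B`, `C`,
#'   `r_squared`, the covered voltage range, and the session id.
#' @export
fit_calibration <- function(sweep, session_id = NULL) {
  stopifnot(is.data.frame(sweep), all(c("power_W", "v_out") %in% names(sweep)))
  sweep <- sweep[is.finite(sweep$power_W) & is.finite(sweep$v_out), , drop = FALSE]
  if (nrow(unique(sweep[c("power_W", "v_out")])) < 4L) {
    stop_sarscan("calibration sweep needs at least 4 distinct points",
                 class = "sarscan_calibration_invalid")
  }
  fit <- lm(power_W ~ I(v_out^2) + v_out, data = sweep)
  cf <- coef(fit)
  if (any(!is.finite(cf))) {
    stop_sarscan("rank-deficient calibration design (voltages not distinct enough)",
                 class = "sarscan_calibration_invalid")
  }
  A <- unname(cf["I(v_out^2)"]); B <- unname(cf["v_out"]); C <- unname(cf["(Intercept)"])
  v_range <- range(sweep$v_out)
  # quadratic derivative 2Av + B is linear: endpoint check suffices
  # (a zero slope exactly at the range edge, e.g. B = 0 at V = 0, is allowed)
  if (min(2 * A * v_range + B) < -1e-9) {
    stop_sarscan("fitted calibration curve is not strictly increasing on the data range",
                 class = "sarscan_calibration_invalid")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((sweep$power_W - mean(sweep$power_W))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(A = A, B = B, C = C, r_squared = r2,
                 v_range = v_range, session_id = session_id),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> P = %.5g V^2 + %.5g V + %.5g  (R^2 = %.6f, V in [%.3g, %.3g])\n",
              x$A, x$B, x$C, x$r_squared, x$v_range[1], x$v_range[2]))
  invisible(x)
}

#' Convert scan voltages to power-proportional values
#'
#' Applies the fitted quadratic to each mean voltage. Small negative values
#' (noise near V = 0 with a negative fitted `C`) are clipped to zero and
#' counted; voltages more than 10% beyond the calibrated range abort, since
#' they indicate a calibration from the wrong session.
#'
#' @param record A `scan_record` (or data frame with a `v_mean` column).
#' @param curve A [fit_calibration()] result.
#' @param check_session If `TRUE` (default), refuse to mix a scan and a
#'   calibration carrying different non-missing session ids.
#' @return The record with a `p_eq` column (W-equivalent); attribute
#'   `n_clipped` counts clipped negatives.
#' @export
voltages_to_power <- function(record, curve, check_session = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"), "v_mean" %in% names(record))
  meta <- attr(record, "metadata")
  if (check_session && !is.null(meta) && !is.null(curve$session_id)) {
    sid <- meta$session_id
    if (!is.null(sid) && !is.na(sid) &&
        !identical(as.character(sid), as.character(curve$session_id))) {
      stop_sarscan("scan session id (", sid, ") does not match calibration session id (",
                   curve$session_id, "); per-session calibration is required",
                   class = "sarscan_session_mismatch")
    }
  }
  v <- record$v_mean
  if (any(v > curve$v_range[2] * 1.1)) {
    stop_sarscan("scan voltages exceed the calibrated range by more than 10%; ",
                 "wrong calibration session?", class = "sarscan_extrapolation")
  }
  span <- diff(curve$v_range)
  scan_span <- diff(range(v))
  if (scan_span > 0 && span < 0.9 * scan_span) {
    warning("calibration sweep covers only ", sprintf("%.0f%%", 100 * span / scan_span),
            " of the scan's voltage range", call. = FALSE)
  }
  p <- curve$A * v^2 + curve$B * v + curve$C
  n_clipped <- sum(p < 0)
  p[p < 0] <- 0
  record$p_eq <- p
  attr(record, "n_clipped") <- n_clipped
  record
}

#' Normalise power-proportional values to relative SAR (percent)
#'
#' The reference is the maximum value among the points at the reference
#' depth (1 cm by default, matched to within half a grid spacing); that
#' point maps to 100%. Values above 100% can occur for depth planes whose
#' maximum lies below the reference row and are permitted with a warning
#' only in the pathological case where no deeper normalisation is intended.
#'
#' @param record Output of [voltages_to_power()] (needs `p_eq` and `depth`).
#' @param reference `"depth_reference"` (default) or `"plane_max"` for
#'   sensitivity checks.
#' @param depth_reference Reference depth, cm.
#' @param spacing Grid spacing used for the depth tolerance; taken from the
#'   record metadata when missing.
#' @return The record with a `sar` column in percent; attribute
#'   `normalization` records the reference value and point.
#' @export
normalize_relative_sar <- function(record, reference = c("depth_reference", "plane_max"),
                                   depth_reference = 1, spacing = NULL) {
  reference <- match.arg(reference)
  stopifnot(all(c("p_eq", "depth") %in% names(record)))
  meta <- attr(record, "metadata")
  spacing <- spacing %||% meta$spacing_cm %||% 1
  if (reference == "depth_reference") {
    at_ref <- abs(record$depth - depth_reference) <= spacing / 2 + 1e-9
    if (!any(at_ref)) {
      stop_sarscan("no points at the ", depth_reference, " cm reference depth",
                   class = "sarscan_no_reference")
    }
    ref_idx <- which(at_ref)[which.max(record$p_eq[at_ref])]
  } else {
    ref_idx <- which.max(record$p_eq)
  }
  ref <- record$p_eq[ref_idx]
  if (!isTRUE(ref > 0)) {
    stop_sarscan("degenerate scan: all power-proportional values are zero",
                 class = "sarscan_degenerate_scan")
  }
  sar <- 100 * record$p_eq / ref
  if (any(sar > 100 + 1e-6)) {
    warning("values above 100%: the scan maximum lies below the reference depth",
            call. = FALSE)
  }
  record$sar <- sar
  attr(record, "normalization") <- list(
    reference_value = ref, reference = reference,
    reference_point = record[ref_idx, intersect(c("u", "v", "depth"), names(record))]
  )
  record
}
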