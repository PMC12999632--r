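#' Virtual applicator: a parametric stand-in for robot, phantom and sensor
#'
#' The simulator replaces the physical setup (Cartesian robot, saline tank,
#' diode E-field sensor, signal generator) with an explicit parametric
#' relative-SAR field plus sensor and noise models, so every stage of the QA
#' pipeline -- calibration, scanning, interpolation, metric extraction -- can
#' run and be tested without hardware. The field model is a tuned stand-in,
#' not an electromagnetic solution; see the methods vignette.
#'
#' @name sarscan-simulator
NULL

#' Saline phantom dielectric properties
#'
#' Defaults are a 3 g/L NaCl solution at 434 MHz and room temperature:
#' conductivity 0.53 S/m, relative permittivity 78.7 (about 2/3 of muscle
#' conductivity).
#'
#' @param conductivity Electrical conductivity sigma, S/m (> 0).
#' @param permittivity Relative permittivity (dimensionless).
#' @param density Mass density rho, kg/m^3 (> 0).
#' @param salinity NaCl concentration, g/L.
#' @return Object of class `phantom_properties`.
#' @export
phantom_properties <- function(conductivity = 0.53, permittivity = 78.7,
                               density = 1000, salinity = 3) {
  stopifnot(conductivity > 0, density > 0)
  structure(list(conductivity = conductivity, permittivity = permittivity,
                 density = density, salinity = salinity),
            class = "phantom_properties")
}

#' Parametric applicator SAR-field model
#'
#' Relative SAR is modelled as a separable-by-default product of lateral
#' Gaussians and an exponential power decay in depth,
#' \deqn{S(u,v,d) = e^{-(u-c_x)^2/2\sigma_x(d)^2} e^{-(v-c_y)^2/2\sigma_y(d)^2}
#'   e^{-2(d-1)/\delta},}
#' with depth-dependent lateral widths \eqn{\sigma(d) = \sigma_0 (1 + \kappa (d-1))}.
#' A non-zero broadening rate `kappa` makes the field non-separable so the
#' penetration depth varies across the aperture. An irregularity mode
#' (amplitude `mod_amplitude`, period `mod_period`) multiplies the field by
#' `1 + m cos(2 pi (u - c_x) / L)`, a standing-wave ripple along the slot
#' axis mimicking the split high-SAR regions seen with excessively thick
#' water boluses. Curvature couples in
#' through `delta * (1 + epd_curvature_gain / radius)` and
#' `sigma_x0 * (1 - efs_curvature_shrink / radius)`.
#'
#' @param aperture_x,aperture_y Aperture size, cm.
#' @param sigma_x0,sigma_y0 Lateral Gaussian widths at the 1 cm plane, cm.
#' @param delta Depth power-decay scale, cm (EPD at the field maximum is
#'   `delta * log(2) / 2` additional depth).
#' @param kappa Lateral broadening rate with depth, 1/cm.
#' @param centre Field-centre offset `c(cx, cy)` in cm relative to the
#'   visually aligned applicator centre.
#' @param curvature_radius Contact-surface curvature radius in cm, `Inf` for flat.
#' @param bolus_cm Water bolus thickness, cm.
#' @param mod_amplitude Irregularity amplitude in `[0, 1)`; defaults to 0.35
#'   when `bolus_cm >= 2` (thick-bolus resonance regime) and 0 otherwise.
#' @param mod_period Irregularity period, cm.
#' @param epd_curvature_gain,efs_curvature_shrink Curvature coupling
#'   coefficients (cm per unit 1/radius).
#' @param phantom A [phantom_properties()].
#' @param name Model identifier stored in scan metadata.
#' @return Object of class `applicator_model`.
#' @export
applicator_model <- function(aperture_x = 19.7, aperture_y = 28.5,
                             sigma_x0 = 8.876, sigma_y0 = 5.308, delta = 7.9,
                             kappa = 0.05, centre = c(0.8, -0.9),
                             curvature_radius = Inf, bolus_cm = 1.3,
                             mod_amplitude = if (bolus_cm >= 2) 0.35 else 0,
                             mod_period = 9,
                             epd_curvature_gain = 1.0, efs_curvature_shrink = 1.0,
                             phantom = phantom_properties(), name = "custom") {
  stopifnot(sigma_x0 > 0, sigma_y0 > 0, delta > 0, mod_period > 0,
            mod_amplitude >= 0, mod_amplitude < 1, length(centre) == 2L)
  structure(list(
    aperture_x = aperture_x, aperture_y = aperture_y,
    sigma_x0 = sigma_x0, sigma_y0 = sigma_y0, delta = delta, kappa = kappa,
    centre = as.numeric(centre), curvature_radius = curvature_radius,
    bolus_cm = bolus_cm, mod_amplitude = mod_amplitude, mod_period = mod_period,
    epd_curvature_gain = epd_curvature_gain, efs_curvature_shrink = efs_curvature_shrink,
    phantom = phantom, name = name
  ), class = "applicator_model")
}

# Curvature-effective parameters.
model_effective <- function(model) {
  R <- model$curvature_radius
  curv <- if (is.finite(R)) 1 / R else 0
  list(sigma_x0 = model$sigma_x0 * (1 - model$efs_curvature_shrink * curv),
       sigma_y0 = model$sigma_y0,
       delta = model$delta * (1 + model$epd_curvature_gain * curv))
}

#' Relative SAR of the model field
#'
#' @param model An [applicator_model()].
#' @param u,v Surface coordinates, cm (vectors, recycled).
#' @param depth Depth below the contact surface, cm (>= 0).
#' @param offset Extra field-centre displacement `c(du, dv)` in cm, used for
#'   per-session positioning offsets.
#' @return Dimensionless relative SAR (1 at the field maximum of the 1 cm
#'   plane when `mod_amplitude = 0`).
#' @export
relative_sar <- function(model, u, v, depth, offset = c(0, 0)) {
  stopifnot(inherits(model, "applicator_model"))
  if (any(depth < 0)) stop_sarscan("depth must be >= 0", class = "sarscan_bad_depth")
  eff <- model_effective(model)
  cx <- model$centre[1] + offset[1]
  cy <- model$centre[2] + offset[2]
  sx <- eff$sigma_x0 * (1 + model$kappa * (depth - 1))
  sy <- eff$sigma_y0 * (1 + model$kappa * (depth - 1))
  val <- exp(-(u - cx)^2 / (2 * sx^2)) * exp(-(v - cy)^2 / (2 * sy^2)) *
    exp(-2 * (depth - 1) / eff$delta)
  if (model$mod_amplitude > 0) {
    # standing-wave ripple along the slot axis: the +/- L/2 troughs drop below
    # the 50% threshold for the whole transverse extent, splitting the region
    val <- val * (1 + model$mod_amplitude * cos(2 * pi * (u - cx) / model$mod_period))
  }
  val
}

#' Diode E-field sensor model
#'
#' A quadratic power-to-voltage response: the equivalent power `P` at the
#' probe satisfies `P = A V^2 + B V + C`, with the voltage obtained as the
#' positive root. The response is strictly increasing on the valid range.
#'
#' @param A,B,C True response coefficients (W/V^2, W/V, W).
#' @param v_range Valid voltage range, volts.
#' @return Object of class `diode_sensor`.
#' @export
diode_sensor <- function(A = 0.02, B = 0.5, C = 0, v_range = c(0, 60)) {
  stopifnot(A > 0, length(v_range) == 2L, v_range[1] < v_range[2])
  if (2 * A * v_range[1] + B <= 0) {
    stop_sarscan("sensor response not strictly increasing on the valid range",
                 class = "sarscan_bad_sensor")
  }
  structure(list(A = A, B = B, C = C, v_range = as.numeric(v_range)),
            class = "diode_sensor")
}

# Invert P = A V^2 + B V + C for the positive root; errors on saturation.
sensor_voltage <- function(sensor, power_eq) {
  disc <- sensor$B^2 + 4 * sensor$A * (power_eq - sensor$C)
  if (any(disc < 0)) {
    stop_sarscan("equivalent power below the sensor floor (no real voltage root)",
                 class = "sarscan_saturation")
  }
  v <- (-sensor$B + sqrt(disc)) / (2 * sensor$A)
  bad <- which(v < sensor$v_range[1] - 1e-9 | v > sensor$v_range[2] + 1e-9)
  if (length(bad)) {
    stop_sarscan("sensor saturation at point index ", bad[1], ": voltage ",
                 sprintf("%.3g", v[bad[1]]), " V outside the valid range",
                 class = "sarscan_saturation")
  }
  v
}

#' Session noise model
#'
#' One positioning offset per session (the applicator and probe are aligned
#' visually once per measurement day), plus independent multiplicative noise
#' on every voltage reading. With the defaults (0.5 cm positioning SD per
#' lateral axis, 0.4% reading SD) the triplicate coefficient of variation is
#' below 1% for over 99% of points.
#'
#' @param position_sd Positioning offset SD per lateral axis, cm.
#' @param reading_sd Per-reading multiplicative noise SD (fraction).
#' @param seed Integer seed; `NULL` uses the current RNG state (so a caller
#'   can seed once per session).
#' @return Object of class `session_noise`.
#' @export
session_noise <- function(position_sd = 0.5, reading_sd = 0.004, seed = NULL) {
  stopifnot(position_sd >= 0, reading_sd >= 0)
  structure(list(position_sd = position_sd, reading_sd = reading_sd, seed = seed),
            class = "session_noise")
}

noise_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  invisible(NULL)
}

draw_session_offset <- function(noise) {
  if (noise$position_sd > 0) rnorm(2, 0, noise$position_sd) else c(0, 0)
}

#' Simulate the triplicate voltage reading at one position
#'
#' The equivalent power at the probe is `generator_power * relative SAR` at
#' the session-offset position; the noiseless voltage is the positive root of
#' the quadratic sensor response, and each of the three readings is
#' multiplied by an independent `1 + N(0, reading_sd)` factor.
#'
#' @param model An [applicator_model()].
#' @param sensor A [diode_sensor()].
#' @param noise A [session_noise()]; its `seed` (if any) is applied first.
#' @param uvd Surface coordinates `c(u, v, depth)` of the point.
#' @param generator_power Generated power, W (>= 0).
#' @param offset Session positioning offset `c(du, dv)`; `NULL` draws one
#'   from the noise model.
#' @return Named vector `c(v1, v2, v3, v_mean)` in volts.
#' @export
virtual_reading <- function(model, sensor, noise, uvd, generator_power, offset = NULL) {
  stopifnot(generator_power >= 0)
  noise_seed(noise)
  if (is.null(offset)) offset <- draw_session_offset(noise)
  sar <- relative_sar(model, uvd[1], uvd[2], uvd[3], offset = offset)
  v0 <- sensor_voltage(sensor, generator_power * sar)
  eps <- if (noise$reading_sd > 0) rnorm(3, 0, noise$reading_sd) else numeric(3)
  v <- v0 * (1 + eps)
  c(v1 = v[1], v2 = v[2], v3 = v[3], v_mean = mean(v))
}

#' Run a virtual scan of a plan
#'
#' Produces one voltage record per plan point, in plan order. The session
#' positioning offset is drawn once per scan (unless supplied), matching the
#' once-per-day visual alignment of the physical procedure.
#'
#' @inheritParams virtual_reading
#' @param plan A [build_scan_plan()] result.
#' @return A `scan_record`: the plan's point table with reading columns
#'   `v1, v2, v3, v_mean` and a `metadata` attribute (power, phantom
#'   properties, applicator/bolus/curvature, seed, session offset truth).
#' @export
run_virtual_scan <- function(plan, model, sensor, noise = session_noise(0, 0),
                             generator_power = 30, offset = NULL) {
  stopifnot(inherits(plan, "scan_plan"), nrow(plan$points) > 0L,
            generator_power >= 0)
  noise_seed(noise)
  if (is.null(offset)) offset <- draw_session_offset(noise)
  pts <- plan$points
  sar <- relative_sar(model, pts$u, pts$v, pts$depth, offset = offset)
  v0 <- tryCatch(sensor_voltage(sensor, generator_power * sar),
                 sarscan_saturation = function(e) stop(e))
  n <- length(v0)
  eps <- if (noise$reading_sd > 0) matrix(rnorm(3 * n, 0, noise$reading_sd), n, 3) else
    matrix(0, n, 3)
  readings <- v0 * (1 + eps)
  rec <- cbind(pts,
               v1 = readings[, 1], v2 = readings[, 2], v3 = readings[, 3],
               v_mean = rowMeans(readings))
  meta <- list(
    schema = "sarscan/scan/1",
    power_W = generator_power,
    conductivity_S_per_m = model$phantom$conductivity,
    permittivity = model$phantom$permittivity,
    salinity_g_per_L = model$phantom$salinity,
    applicator = model$name,
    bolus_cm = model$bolus_cm,
    curvature_cm = if (is.finite(model$curvature_radius)) model$curvature_radius else NA,
    plane_kind = plan$plane_kind,
    spacing_cm = plan$spacing,
    depth_reference_cm = plan$depth_reference,
    seed = noise$seed,
    session_offset_cm = as.numeric(offset),
    date = NA,
    session_id = noise$seed %||% NA
  )
  structure(rec, metadata = meta, class = c("scan_record", "data.frame"))
}

#' Simulate a sensor calibration sweep
#'
#' The probe sits at a fixed high-SAR position at the reference depth while
#' the generator steps through `powers`; the mean triplicate voltage is
#' recorded per power. A warning is raised if the chosen point sees less
#' than 90% of the plane's maximum relative SAR, since the sweep would then
#' not cover the full voltage range encountered in scans.
#'
#' @inheritParams virtual_reading
#' @param powers Generated powers, W (default 0 to 50 W in 5 W steps).
#' @param point Surface coordinates `c(u, v, depth)` of the calibration
#'   position (default: the visually aligned applicator centre at 1 cm).
#' @return Data frame with columns `power_W`, `v_out` and attribute
#'   `relative_sar` (true relative SAR at the offset calibration point).
#' @export
run_calibration_sweep <- function(model, sensor, noise = session_noise(0, 0),
                                  powers = seq(0, 50, by = 5),
                                  point = c(0, 0, 1), offset = NULL) {
  stopifnot(all(powers >= 0), length(point) == 3L)
  noise_seed(noise)
  if (is.null(offset)) offset <- draw_session_offset(noise)
  sar <- relative_sar(model, point[1], point[2], point[3], offset = offset)
  peak <- relative_sar(model, model$centre[1] + offset[1], model$centre[2] + offset[2],
                       point[3], offset = offset)
  if (sar < 0.9 * peak) {
    warning("calibration point sees only ", sprintf("%.0f%%", 100 * sar / peak),
            " of the plane maximum SAR; the sweep may not cover the full voltage range",
            call. = FALSE)
  }
  v0 <- sensor_voltage(sensor, powers * sar)
  n <- length(v0)
  eps <- if (noise$reading_sd > 0) matrix(rnorm(3 * n, 0, noise$reading_sd), n, 3) else
    matrix(0, n, 3)
  vm <- rowMeans(v0 * (1 + eps))
  structure(data.frame(power_W = powers, v_out = vm),
            relative_sar = sar, session_offset = offset)
}

# Continuous-field EPD (additional depth) of the column at surface position
# (u, v): solves S(u, v, 1 + e) = S(u, v, 1) / 2 for e.
analytic_column_epd <- function(model, u, v, upper = 60) {
  ref <- relative_sar(model, u, v, 1)
  f <- function(e) relative_sar(model, u, v, 1 + e) - ref / 2
  uniroot(f, c(1e-6, upper), tol = 1e-10)$root
}

#' Tune the depth-decay scale to a target penetration depth
#'
#' Lateral widths follow in closed form from EFS targets
#' (`sigma = EFS / (2 sqrt(2 log 2))`); the depth scale `delta` is found by a
#' 1-D root search so that the EPD evaluated on the central xz-plane column
#' (at the lateral position of that plane's maximum, v = 0) equals the
#' target. With a field-centre offset in y and non-zero broadening `kappa`
#' this differs slightly from the closed form `delta log(2) / 2`.
#'
#' @param model An [applicator_model()] whose `delta` is to be replaced.
#' @param epd_target Target EPD (additional depth beyond the 1 cm plane), cm.
#' @return The model with tuned `delta`.
#' @export
tune_delta_to_epd <- function(model, epd_target) {
  f <- function(delta) {
    m <- model; m$delta <- delta
    analytic_column_epd(m, m$centre[1], 0) - epd_target
  }
  delta <- uniroot(f, c(0.5, 40), tol = 1e-10)$root
  model$delta <- delta
  model
}

fwhm_factor <- 2 * sqrt(2 * log(2))

#' Scenario presets
#'
#' Named presets of the form `"<applicator>-<setup>-<bolus>"`, e.g.
#' `"5H-flat-1.3"`, `"3H-r17.5-1.3"`, `"5H-flat-2.5"`. The 5H lateral widths
#' and depth decay are tuned so that the noiseless flat pipeline reproduces
#' EFS 20.9 x 12.5 cm and EPD 2.74 cm; the 3H widths reproduce
#' EFS 15.2 x 20.4 cm. Bolus thickness at or above 2 cm switches on the
#' irregularity mode that splits the 50% isoline.
#'
#' @param name Preset name.
#' @return An [applicator_model()].
#' @export
scenario_preset <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !parts[1] %in% c("3H", "5H")) {
    stop_sarscan("unknown scenario preset: ", name,
                 " (expected e.g. '5H-flat-1.3', '3H-r17.5-2.5')",
                 class = "sarscan_bad_scenario")
  }
  radius <- if (identical(parts[2], "flat")) Inf else {
    r <- suppressWarnings(as.numeric(sub("^r", "", parts[2])))
    if (!isTRUE(r > 0)) stop_sarscan("bad curvature in preset: ", name,
                                     class = "sarscan_bad_scenario")
    r
  }
  bolus <- suppressWarnings(as.numeric(parts[3]))
  if (!isTRUE(bolus > 0)) stop_sarscan("bad bolus thickness in preset: ", name,
                                       class = "sarscan_bad_scenario")
  base <- switch(parts[1],
    "5H" = applicator_model(aperture_x = 19.7, aperture_y = 28.5,
                            sigma_x0 = 20.9 / fwhm_factor, sigma_y0 = 12.5 / fwhm_factor,
                            curvature_radius = radius, bolus_cm = bolus, name = name),
    "3H" = applicator_model(aperture_x = 28.7, aperture_y = 20.8,
                            sigma_x0 = 15.2 / fwhm_factor, sigma_y0 = 20.4 / fwhm_factor,
                            curvature_radius = radius, bolus_cm = bolus, name = name))
  # tune the flat-setup depth decay to EPD 2.74 cm, then re-apply curvature
  flat <- base; flat$curvature_radius <- Inf; flat$mod_amplitude <- 0
  tuned <- tune_delta_to_epd(flat, 2.74)
  base$delta <- tuned$delta
  base
}
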