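# Shared fixture builders. Everything is generated in code; no data files.

default_frame <- function() coordinate_frame()

test_bbox <- function(zmax = 6) bounding_box(c(-16, 16), c(-12, 12), c(0, zmax))

# Noiseless full-pipeline session for a model: returns analysed records and
# metrics for the requested plane kinds.
noiseless_session <- function(model, planes = c("xy", "xz"), spacing = 1,
                              bbox = test_bbox(), surface = flat_surface(),
                              power = 30) {
  fr <- default_frame()
  plan_of <- function(kind) switch(kind,
    xy = build_scan_plan(surface, fr, bbox, "xy_at_depth", spacing),
    xz = build_scan_plan(surface, fr, bbox, "xz", spacing, depth_range = c(1, bbox$zlim[2])),
    yz = build_scan_plan(surface, fr, bbox, "yz", spacing, depth_range = c(1, bbox$zlim[2])),
    volume = build_scan_plan(surface, fr, bbox, "volume", spacing, depth_range = c(1, bbox$zlim[2])))
  plans <- setNames(lapply(planes, plan_of), planes)
  run_qa_session(model, diode_sensor(), plans, session_noise(0, 0), power)
}

# Raster record built directly from a closed-form field, bypassing the
# simulator and calibration (independent input for the metrics module).
field_record <- function(f, u = seq(-16, 16, 1), v = seq(-12, 12, 1), depth = 1,
                         spacing = min(diff(sort(unique(u))))) {
  g <- expand.grid(u = u, v = v, depth = depth)
  g$sar <- f(g$u, g$v, g$depth)
  structure(g, metadata = list(spacing_cm = spacing, plane_kind = "synthetic"),
            class = c("scan_record", "data.frame"))
}

fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma
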