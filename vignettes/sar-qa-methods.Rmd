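---
title: "Methods: automated relative-SAR QA for hyperthermia applicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated relative-SAR QA for hyperthermia applicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarscan)
```

## The problem

Superficial microwave hyperthermia heats tumours a few centimetres below the
skin with radiative applicators (e.g. 434 MHz contact flexible microstrip
applicators, CFMAs). Consistent treatment quality requires periodic
dosimetric characterization of each applicator: does it still deposit power
where and how deep it should? The accepted QA metrics are:

* **EFS** (effective field size): the extent of the region above 50% of the
  maximum relative SAR in the plane 1 cm below the bolus--phantom interface,
  reported as the extreme extensions of the 50% contour along the main axes,
  EFS\(_x \times\) EFS\(_y\), plus its area;
* **EPD** (effective penetration depth): the additional depth, beyond the
  1 cm plane, at which SAR falls to 50% of its value at 1 cm, evaluated at
  (or near) the maximum-SAR position;
* **centre shifts** \(\Delta_x, \Delta_y\): the offset of the 50%-contour
  midpoint from the visually aligned applicator centre, a proxy for
  positioning accuracy and field asymmetry.

SAR is proportional to the squared electric field,
\(\mathrm{SAR} = \sigma |E|^2 / (2\rho)\), so for a fixed probe position the
power sensed by a diode E-field probe is proportional to the generator
power. Scanning a probe through a saline phantom with a Cartesian robot and
converting voltages to power-proportional values therefore yields *relative*
SAR maps -- fully sufficient for the metrics above, which are all ratios.

`sarscan` implements that workflow end to end: scan-plan and G-code
generation (flat and cylindrically curved contact surfaces), quadratic diode
calibration, interpolation of scanned planes to a fine analysis grid, the
metrics, and the three studies that qualify a routine protocol (spatial
resolution, repeatability, applicator characterization). A *virtual
applicator* replaces the hardware so the whole pipeline runs at desk scale.

## Coordinate frames and curved geometry

The measurement frame follows the IEC 61217 fixed reference system with the
origin at the applicator centre on the bolus--phantom interface and the
z axis re-signed to grow with depth; the robot frame is linked through an
explicit `coordinate_frame(origin_in_robot, z_sign_flip)`. The robot's
native axis conventions are vendor-specific, so the z flip is a declared
field of the frame rather than an assumption.

Curved setups model the contact sheet as a cylinder whose axis runs along
y; the apex of the trough is the measurement origin and phantom depth
increases radially *outward*, so a point at depth \(d\) sits at distance
\(R + d\) from the axis. The practical alignment procedure -- jog the probe
to three points at 1 cm depth, fit the circle through them
(`circle_from_three_points`, with a collinearity guard at triangle area
\(< 10^{-9}\,\mathrm{cm}^2\)) -- recovers the axis and radius. Surface
coordinates \((u, v, \text{depth})\) use the signed arc length \(u = R\theta\);
flat geometry is exactly the \(R \to \infty\) limit (verified to
\(10^{-3}\) cm at \(R = 10^4\) m over a 30 cm aperture).

Scan plans are phase-anchored: grid nodes sit at integer multiples of the
spacing from the measurement origin. This guarantees the applicator centre
is always sampled and makes coarser grids *strict subsets* of finer ones,
which is what turns the resolution study into a pure subsetting operation.
Whether the clinical procedure anchored grids at the applicator centre or a
tank corner is not documented anywhere we could rely on; centre-anchoring
was chosen for this subsetting property. Bounding boxes are interpreted in
surface coordinates (arc length along the curvature), matching how scan
limits are set from the applicator extent. Depth scans emit the 1 cm
reference curve first, then fill the box boustrophedon by increasing depth.
G-code output is deliberately minimal -- metric (`G21`), absolute (`G90`),
one `G1` move per point in robot millimetres, a `G4` dwell of 0.8 s, and a
`(READ n=3)` comment marker; the scan runner, not the motion file, triggers
the voltage readings.

## The virtual applicator

No functional form of a true CFMA SAR field is published, so the simulator
is an explicit parametric stand-in -- the smallest model that exercises
every metric, *not* an electromagnetic solution:

\[
S(u, v, d) = \exp\!\Big(-\tfrac{(u - c_x)^2}{2\sigma_x(d)^2}\Big)
\exp\!\Big(-\tfrac{(v - c_y)^2}{2\sigma_y(d)^2}\Big)
\exp\!\Big(-\tfrac{2 (d - 1)}{\delta}\Big),
\qquad \sigma(d) = \sigma_0 \big(1 + \kappa (d - 1)\big).
\]

| parameter | meaning | default (5H preset) | origin |
|---|---|---|---|
| \(\sigma_{x0}, \sigma_{y0}\) | lateral widths at 1 cm | 8.88, 5.31 cm | EFS targets 20.9 x 12.5 cm via \(\sigma = \mathrm{EFS}/(2\sqrt{2\ln 2})\) |
| \(\delta\) | depth power-decay scale | 7.87 cm | 1-D root search so the central-plane EPD is 2.74 cm |
| \(\kappa\) | lateral broadening per cm depth | 0.05 cm\(^{-1}\) | chosen small; makes the field non-separable |
| \((c_x, c_y)\) | field-centre offset | (0.8, -0.9) cm | measured mean centre shifts |
| \(m, \Lambda\) | thick-bolus ripple | 0.35, 9 cm (bolus \(\ge\) 2 cm) | chosen so the 50% region splits |
| curvature coupling | \(\delta\!\cdot\!(1 + 1/R)\), \(\sigma_{x0}\!\cdot\!(1 - 1/R)\) | gain/shrink 1 cm | qualitative: EPD grows, EFS\(_x\) shrinks with curvature |

Design notes:

* **Non-separability.** With \(\kappa > 0\) the penetration depth varies
  across the aperture, so the EPD-variation map \(\Delta\mathrm{EPD}(x,y)\)
  is non-trivial; with \(\kappa = 0\) the field is separable and
  \(\Delta\mathrm{EPD} \equiv 0\), a property the test suite checks through
  the full pipeline.
* **Thick-bolus irregularity.** Resonance effects under an excessive bolus
  are emulated by a standing-wave ripple along the slot axis,
  \(1 + m\cos(2\pi (u - c_x)/\Lambda)\). A 1-D ripple is used deliberately:
  a 2-D checkerboard \(\cos u \cos v\) modulation keeps the 50% region
  connected through diagonal saddles (both cosines \(-1\) restores the
  factor \(1 + m\)), whereas the observed phenomenon is a genuine split of
  the 50% region. At \(m = 0.35\), \(\Lambda = 9\) cm the 5H preset splits
  into three components.
* **Depth-decay tuning.** At the field maximum the lateral factors cancel,
  so EPD there is exactly \(\delta \ln 2 / 2\). The central xz-plane sits at
  \(v = 0\), off the field centre \(c_y\), where the \(\kappa\)-broadening
  slightly inflates EPD; \(\delta\) is therefore tuned by a 1-D root search
  on the analytic central-plane column rather than by the closed form.
* **Sensor.** A quadratic power--voltage response
  \(P = A V^2 + B V + C\) with invented truth \(A = 0.02\), \(B = 0.5\),
  \(C = 0\) (strictly increasing over the valid range); the calibration
  module never sees these coefficients directly.
* **Noise.** One positioning offset per *session* (visual alignment happens
  once per measurement day), SD 0.5 cm per lateral axis; depth positioning
  is taken as exact (robot accuracy is sub-millimetre). Reading noise is
  multiplicative, SD 0.4% per reading, three readings per point. "Triplicate
  variation below 1%" is interpreted as the coefficient of variation of the
  three readings: with 0.4% per-reading noise a max-minus-min definition
  would be violated far more than 1% of the time, so only the CV (or
  similar) reading makes the stated noise level self-consistent.
* All randomness flows through one seeded generator recorded in the scan
  metadata.

What the simulator does **not** emulate: true CFMA electromagnetics
(aperture ringing, feed asymmetries), fat layers, air-pocket physics (only
its net repeatability effect), bolus temperature drift. A green test
therefore establishes the correctness of the *analysis pipeline* against a
known field, and that the printed summary metrics are reproduced by the
stated synthetic world -- not that the field model predicts a real
applicator.

## Calibration and normalisation

The quadratic response is linear in \((A, B, C)\), so "nonlinear least
squares" reduces to ordinary least squares -- the fit is exact on noiseless
sweeps (coefficients recovered to \(10^{-8}\) relative). Guard rails follow
the measurement practice:

* a calibration point seeing \(< 90\%\) of the plane maximum, or a sweep
  spanning \(< 90\%\) of a scan's voltage range, raises a coverage warning;
* scan voltages \(> 110\%\) of the calibrated maximum abort (wrong session's
  curve);
* a fitted curve that is not strictly increasing on the data range is
  rejected (zero slope exactly at the range edge is allowed -- that is the
  exact-fit \(B = 0\) case);
* negative fitted powers are clipped to zero and counted, so a miscalibrated
  \(C\) stays visible;
* each scan is normalised to 100% at the maximum value among its *own*
  points at the 1 cm reference depth (tolerance half a grid spacing), per
  scan and per session; mixing a scan with another session's calibration is
  refused unless overridden.

## Grids, metrics and numerical choices

**Interpolation.** Scanned planes are interpolated to a 0.1 cm grid.
Because every plane this pipeline produces is a phase-anchored raster,
piecewise-linear interpolation is implemented as exact bilinear
interpolation on the measurement rectangles (equivalent to triangulated
linear interpolation up to the in-cell diagonal choice, and exact at the
measurement points). Arbitrary scattered point clouds are rejected rather
than approximated -- no Delaunay machinery is shipped.

**EFS.** The extremes of the 50% contour are taken over the
marching-squares contour vertices pooled with the at-or-above-level cell
centres, which resolves the crossing to sub-cell precision; the region area
is the cell count times 0.01 cm\(^2\). All connected components are pooled
(split thick-bolus isolines contribute their full extent). A region
touching the grid boundary raises a truncation warning. The cell-set
extremes serve as the independent oracle in tests: each extreme agrees
within one fine cell, hence spans within two.

**EPD.** Along the chosen column the crossing of 50% of the own 1 cm value
is located by linear interpolation between depth samples -- the first
*downward* crossing, which is robust to non-monotone noise at depth.
Linear interpolation between 1 cm depth samples carries a small convex-chord
offset (about +0.02 cm at the default decay; the closed-form unit tests
sample depth at 0.25 cm where the offset is negligible). EPD is reported as
*additional* depth beyond the 1 cm plane -- the guideline wording is
ambiguous, so a `from_interface` convention flag re-expresses it as depth
below the bolus--phantom interface (+1 cm). Ties in the plane maximum break
towards the smallest \(|u|\); in the volume, towards the smallest distance
to the origin, then lexicographically. Columns with no crossing are
censored and flagged, not extrapolated; a censored max-SAR column is an
error (volume too shallow).

**\(\Delta\)EPD map.** \(\Delta\mathrm{EPD}(x,y) = (\mathrm{EPD}(x,y) -
\mathrm{EPD}_{\max})/\mathrm{EPD}_{\max}\times 100\%\). The "within 5%"
region uses \(|\Delta\mathrm{EPD}| \le 5\%\) -- the source material plots
signed values but does not state whether the region is signed; the signed
map is retained in the output so either reading can be reproduced. The map
also reports whether the central x and y axes pass through the region: if
they do, the central xz/yz planes estimate EPD within the threshold and no
extra max-SAR-positioned scan is needed. The characterization workflow
applies the same rule of thumb prospectively through an 80% axis gate
(configurable 80--90): if the xy-plane's \(\ge 80\%\) region does not
intersect the central axis, the report demands an extra scan.

**Repeatability statistics.** SD is the sample standard deviation
(\(n - 1\) denominator; the source table does not state the denominator,
\(n-1\) is the statistical default), SD% divides by the absolute mean.
Sessions are fully independent pipelines, each with its own positioning
offset and calibration. Sessions with censored EPD are excluded from the
EPD summary and noted.

## Limitations

* The simulator's parameters are tuned to printed summary metrics only; its
  curvature coupling is qualitative (direction, not magnitude, is asserted).
* EFS shape descriptors beyond axis extents and area, and uncertainty
  propagation through interpolation, are out of scope.
* The interpolator requires complete raster scans; partially failed scans
  must be re-run or trimmed to a complete rectangle first.
* Hardware drivers (robot, multimetre, conductivity meter) are explicitly
  out of scope; `emit_gcode` output is a motion program for an external
  runner.

## A complete desk run

```{r}
model <- scenario_preset("5H-flat-1.3")
plans <- list(
  xy = build_scan_plan(flat_surface(), coordinate_frame(),
                       bounding_box(c(-16, 16), c(-12, 12), c(0, 6)),
                       "xy_at_depth", spacing = 1),
  xz = build_scan_plan(flat_surface(), coordinate_frame(),
                       bounding_box(c(-16, 16), c(-12, 12), c(0, 6)),
                       "xz", spacing = 1))
ses <- run_qa_session(model, diode_sensor(), plans,
                      session_noise(0.5, 0.004, seed = 1))
ses$metrics$efs
ses$metrics$epd_xz
```

```{r}
rep8 <- repeatability_study("5H-flat-1.3", n_sessions = 8, seeds = 1:8)
rep8
```
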