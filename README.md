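# sarscan

Automated, SAR-based dosimetric quality assurance for radiofrequency and
microwave hyperthermia applicators.

## What it is for

Clinics delivering superficial hyperthermia must regularly verify that each
applicator still deposits power where and how deep it should. The
established way to do that quantitatively is to scan an E-field probe
through a saline phantom under the applicator with a Cartesian robot,
convert the probe voltages into relative specific absorption rate (SAR)
maps, and extract two guideline metrics:

- **EFS** (effective field size) — the extent of the region above 50% of the
  maximum SAR in the plane 1 cm below the bolus–phantom interface, reported
  as EFS_x × EFS_y (the extreme extensions of the 50% contour along the
  applicator's main axes) together with its area and the centre shifts
  (Δx, Δy) of the contour midpoint from the visually aligned centre;
- **EPD** (effective penetration depth) — the additional depth beyond the
  1 cm plane at which SAR falls to 50% of its value at 1 cm, evaluated at
  (or near) the maximum-SAR position:
  `SAR(d_EPD + 1 cm) = 0.5 · SAR(1 cm)`.

Relative SAR suffices because `SAR = σ|E|²/2ρ` is proportional to the
generator power: a per-session quadratic diode calibration
`P = A·V² + B·V + C` converts voltages to power-proportional values, which
are normalised to 100% at the 1 cm-depth maximum of each scan.

`sarscan` implements the full pipeline for medical physicists and QA
developers:

- scan-plan construction and G-code export for flat and cylindrically
  curved contact surfaces (three-point circle fit, arc-length grids,
  origin-anchored spacing, boustrophedon ordering);
- diode-sensor calibration with coverage/extrapolation/session guards;
- interpolation of scanned planes to a 0.1 cm analysis grid, isoline
  extraction, EFS/EPD/centre-shift computation, and the EPD-variation map
  `ΔEPD(x,y) = (EPD(x,y) − EPD(maxSAR))/EPD(maxSAR) × 100%` with its
  |ΔEPD| ≤ 5% region and axis-crossing check;
- the three studies that qualify a routine protocol: spatial resolution,
  repeatability across measurement days, and applicator characterization
  across curvature/bolus conditions;
- a **virtual applicator** (parametric SAR field + diode sensor + session
  noise models) standing in for robot, phantom and sensor, so everything
  above runs and is testable without hardware.

## Worked example

One simulated measurement session of the default flat 5H-like preset
(tuned so the noiseless pipeline reproduces EFS 20.9 × 12.5 cm and
EPD 2.74 cm), followed by an eight-session repeatability study:

```r
library(sarscan)

model <- scenario_preset("5H-flat-1.3")
bb    <- bounding_box(c(-16, 16), c(-12, 12), c(0, 6))
plans <- list(
  xy = build_scan_plan(flat_surface(), coordinate_frame(), bb, "xy_at_depth", spacing = 1),
  xz = build_scan_plan(flat_surface(), coordinate_frame(), bb, "xz", spacing = 1))

ses <- run_qa_session(model, diode_sensor(), plans,
                      session_noise(0.5, 0.004, seed = 1))
ses$metrics$efs
#> <qa_metrics> EFS 20.91 x 12.54 cm, centre shift (+0.51, -0.81) cm, area 205.2 cm^2, 1 component(s) at 50%
ses$metrics$epd_xz
#> <epd_result> EPD = 2.761 cm (additional depth), column at 0.00 cm

repeatability_study("5H-flat-1.3", n_sessions = 8, seeds = 1:8)
#> <repeatability_result> 8 sessions
#>  metric   mean    sd sd_pct
#>   efs_x 20.926 0.029   0.1%
#>   efs_y 12.527 0.026   0.2%
#>      dx  0.764 0.538      -
#>      dy -0.904 0.416      -
#>  epd_xz  2.762 0.028   1.0%
#>  epd_yz  2.747 0.021   0.8%
```

Reading this: with a 0.5 cm per-axis visual-positioning uncertainty and
0.4% reading noise per voltage sample, the field size and penetration depth
are reproducible to ~1% between sessions; the mean centre shifts recover
the simulator's true field-centre offset (0.8, −0.9) cm, and their SDs
(~0.5 cm) reflect the positioning uncertainty itself. The session
singleton shows one connected 50% region — an excessive bolus preset
(e.g. `"5H-flat-2.5"`) splits it, which `characterize_applicator()` reports
via the component count.

A command-line interface wrapping the same functions is installed at
`inst/cli/sarscan` (subcommands `plan`, `simulate`, `calibrate`, `analyze`,
`qa-resolution`, `qa-repeatability`, `characterize`, `report`).

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline's headline studies from scratch
against the installed package and writes their quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It recomputes: the absolute EPD difference at the 5% ΔEPD boundary for a
2.6 cm EPD; the maximum relative EFS difference between 1/2/4 cm
resamplings of a noiseless 0.25 cm plane and its reference; the maximum
between-session SD% of EFS_x, EFS_y and EPD over eight noisy sessions; and
the relative error between central-plane and max-SAR EPD on a
non-separable volume. The seed drives every random draw; the script reads
nothing outside the repository.

## Scope

Physical hardware drivers (robot, multimetre, conductivity meter),
temperature-rise/infrared QA, full-wave electromagnetic simulation and
clinical treatment planning are out of scope. See
`vignettes/sar-qa-methods.Rmd` for the model, assumptions, numerical
choices and limitations.
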