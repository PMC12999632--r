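Package: sarscan
Title: Automated SAR-Based Dosimetric Quality Assurance for Hyperthermia
    Applicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated quality assurance of radiofrequency and
    microwave hyperthermia applicators from relative specific absorption
    rate (SAR) measurements in liquid phantoms. Provides scan-plan and
    G-code generation for flat and cylindrically curved contact surfaces,
    quadratic diode-sensor calibration, interpolation of scanned voltage
    maps to relative-SAR grids, and the QA metrics effective field size
    (EFS), effective penetration depth (EPD), centre shifts and EPD
    variation maps. A parametric virtual applicator (simulator) stands in
    for the physical robot, phantom and sensor so that spatial-resolution,
    repeatability and applicator-characterization studies can be run and
    tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
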