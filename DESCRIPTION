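Package: padflow
Title: Lumped-Parameter Electrical-Analog Modelling of Arterial Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-dimensional (0D) lumped-parameter modelling of focal
    arterial stenosis built on the classical hemodynamic-electrical analogy:
    pressure is voltage, flow is current, and a vessel segment maps to an
    R-L-C triplet (Poiseuille resistance, fluid inertance, wall compliance).
    Provides a composite viscous-plus-form pressure-loss model with
    fractional flow reserve (FFR), throat velocity and wall shear stress
    outputs; a complex modified-nodal-analysis (MNA) solver for the
    printed-circuit-board analog network with oscilloscope-style
    measurements and supply-rail clipping; voltage-to-pressure calibration
    with bootstrap confidence intervals; axisymmetric cosine-throat stenosis
    geometry with STL export; quasi-steady pulsatile driving and a
    three-element Windkessel terminal load; a validation-statistics toolkit
    (quadratic and segmented fits, discrete Frechet distance, one-at-a-time
    sensitivity, repeatability); and clinical ankle-brachial-index and
    Doppler concordance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
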