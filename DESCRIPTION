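Package: kmrisk
Title: Windowed Progression-Risk Curves, Rebound Detection, and RMST
    Comparison from Patient-Level or Digitized Kaplan-Meier Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing time-dependent treatment effects in
    two-arm trials when the proportional-hazards assumption fails.
    Reconstructs per-day survival either from patient-level records
    (Kaplan-Meier) or from digitized survival-curve coordinates with
    axis calibration; computes windowed progression-risk and smoothed
    relative-risk curves with an explicit incalculability rule; detects
    sustained post-discontinuation excess risk (rebound); and compares
    arms by restricted mean survival time overall and before/after a
    landmark, with optional inverse-probability-weighted covariate
    adjustment. Includes a piecewise-hazard trial simulator and a
    curve-rasterization fixture generator so the whole pipeline is
    testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    graphics,
    grDevices,
    tools,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
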