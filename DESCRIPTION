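Package: vmatcx
Title: Beam Complexity Analysis for Volumetric Modulated Arc Therapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses arc-therapy DICOM RT Plan files into an in-memory model of
    control points, multileaf-collimator (MLC) apertures and monitor-unit
    weights, and computes per-segment and per-arc beam-complexity scores:
    segment width (SW), segment area (SA), leaf sequence variability (LSV),
    aperture area variability (AAV) and the modulation complexity score (MCS).
    Includes machine-geometry templates for a 60-pair mixed-width MLC and a
    40-pair 10 mm MLC, a forward kinematic estimator of per-segment gantry
    speed, dose rate and beam-on time under continuous or binned dose-rate
    control, a synthetic arc-plan generator with controlled modulation, and
    paired two-sided Wilcoxon signed-rank cohort comparisons with
    mean/standard-deviation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
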