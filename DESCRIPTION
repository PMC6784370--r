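Package: gmrflow
Title: Simulation and Signal Analysis for Magnetoresistive In-Flow Cell Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Physics-based simulator and signal-analysis toolkit for giant
    magnetoresistance (GMR) biosensor cell counters. Computes the in-plane
    dipolar field of magnetically labeled cells and bead aggregates averaged
    over a rectangular sensing element (closed form plus a quadrature oracle),
    generates statistically calibrated synthetic samples and voltage traces
    through the amplification chain, implements the rule-based bipolar peak
    detector used to discriminate cell transits from noise artifacts, derives
    separation-layer design curves (detectable height versus bead load), and
    provides the counting statistics used to declare a sample positive
    (negative-control count thresholds, blank-based limits of detection and
    quantification).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
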