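Package: xpanderdose
Title: Metallic-Port Tissue-Expander Modeling for Photon Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the high-density magnetic injection port found in temporary
    breast tissue expanders for photon radiotherapy treatment planning. Provides a
    parametric tilted-disk port geometry with analytic ray-chord queries, slice
    contour generation and rasterization; seeded synthetic phantom generators
    (ion-chamber water tank, inflated/deflated simplified anthropomorphic phantoms,
    a patient-like chest phantom) with CT metal-artifact simulation and
    Hounsfield-to-density conversion tables; a heterogeneity-corrected percent-depth-dose
    photon dose engine with Siddon radiological path lengths, wedges, arcs and plan
    composition; a grid-search calibration that recovers port density and dimensions
    from depth-dose measurements; and evaluation tooling (percent-difference
    comparison tables, cumulative dose-volume histograms, reduced planning target
    volumes, full-width-at-half-maximum port dimensioning, thermoluminescent
    dosimeter calibration fits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
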