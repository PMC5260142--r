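Package: stentkrig
Title: Kriging Surrogate Multi-Objective Optimization of Coronary Stent
    Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive Kriging (Gaussian-process) surrogate optimization of
    balloon-expandable coronary stent expansion performance.  Implements the
    dogboning-ratio and radial-elastic-recoil metrics with weighted-sum
    scalarization over sample-adaptive normalization bounds, modified
    rectangular grid (MRG) design of experiments with a provable minimum
    pairwise spacing, ordinary Kriging fitted by concentrated maximum
    likelihood, expected-improvement (EGO) infill sampling with a three-part
    convergence test, and a reduced-order analytic balloon-stent expansion
    simulator with binary-search inflation-pressure calibration standing in
    for finite-element evaluations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
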