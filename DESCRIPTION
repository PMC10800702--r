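Package: ahparas
Title: Hybrid AHP-ARAS Multi-Criteria Decision Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives criterion weights from expert pairwise-comparison
    matrices on the Saaty 1-9 scale with full consistency diagnostics
    (lambda-max, consistency index and ratio), and ranks alternatives by
    additive ratio assessment (ARAS) utility degrees against those weights.
    Includes validated readers for labelled CSV decision and judgment
    matrices, a synthetic scenario generator with controllable judgment
    inconsistency for parameter-recovery and robustness studies, weight
    perturbation and criterion-knockout sensitivity analyses, JSON study
    reports, and a command-line interface. Ships the worked example of an
    eight-criterion evaluation of eight computer-based health-monitoring
    applications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
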