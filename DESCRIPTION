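Package: mraxis
Title: Two-Sample Mendelian Randomization and Mediation Pipeline for
    Regulatory-Axis Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summary-statistics causal inference for molecular epidemiology:
    instrument selection (genome-wide significance, minor-allele-frequency
    and instrument-strength filters, greedy LD clumping against a
    user-supplied reference panel), allele harmonization between exposure
    and outcome studies including palindromic-variant resolution from
    allele frequencies, five two-sample Mendelian randomization estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple and
    weighted mode) behind a single fitting function with the usual S3
    methods, a sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO
    outlier detection, Steiger directionality, leave-one-out), two-step
    delta-method mediation with proportion screening, and an orchestrated
    multi-layer screen that assembles exposure-mediator-metabolite-outcome
    regulatory axes. A synthetic summary-statistics generator with known
    ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
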