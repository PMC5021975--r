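Package: seawas
Title: Season-Wide Association Scans of Birth Month and Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for season-wide association studies on electronic health
    record cohorts. For every diagnosis code the scan tests whether patients'
    birth-month distribution differs from the population's, computes the
    twelve-point birth-month relative-risk curve with Katz log-method
    confidence intervals, and controls the false discovery rate across the
    phenome with the Benjamini-Hochberg procedure. A permutation test
    compares birth-month risk curves between two institutions via Pearson
    correlation against an empirical null obtained by shuffling one curve.
    Includes a synthetic two-institution cohort generator with known injected
    seasonal effects for calibration and power studies, readers for flat
    patient/diagnosis/mapping tables, and publication-style summary outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
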