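Package: fusioncall
Title: Gene Fusion Calling and QC for nCounter Leukemia Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation pipeline for hybridization-count gene fusion
    panels run on the NanoString nCounter platform, as used for pediatric
    leukemia diagnosis. Reads per-lane RCC files and wide count tables,
    calibrates per-probe background positivity cutoffs (mean + 3 and + 5
    standard deviations over fusion-negative samples), gates lanes on
    internal assay controls and housekeeping-gene RNA quality, calls
    fusion-positive samples with repeat-testing and reflex recommendations,
    checks concordance against flow-cytometry immunophenotypes, renders
    color-coded run reports, and simulates complete runs with ground truth
    for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
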