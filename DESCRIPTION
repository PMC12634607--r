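Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FAERS-style spontaneous
    adverse-event report bundles: multi-version case deduplication, primary-
    suspect cohort construction, reporting odds ratio (ROR) and proportional
    reporting ratio (PRR) disproportionality statistics with 95% confidence
    intervals and signal classification, aggregation to ATC therapeutic
    classes, time-to-onset binning, and demographic summaries. Includes a
    synthetic FAERS-like report generator with planted association strengths
    so the full pipeline can be exercised and validated without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
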