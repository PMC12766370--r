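Package: faerspv
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    adverse-event reports in the FDA Adverse Event Reporting System (FAERS)
    quarterly ASCII dialect: ingestion and round-trip writing of the
    DEMO/DRUG/REAC/THER/OUTC tables, case deduplication by the FDA
    CASEID/FDA_DT/PRIMARYID rule, drug-name standardization and ATC
    classification through auditable dictionary maps, reporting odds ratio
    (ROR) and Bayesian confidence propagation neural network (BCPNN)
    information-component statistics with dual-criterion signal calls and
    IC025-based strength stratification, strict-date time-to-onset
    summaries, and descriptive reporting. Includes a synthetic FAERS-like
    quarter generator with planted drug-event associations, duplicate
    report versions and malformed dates, so the full pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
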