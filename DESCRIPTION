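Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance analysis of individual case
    safety reports (ICSRs): ingestion and normalization of relational report
    tables with inclusion, exclusion and deduplication rules; descriptive
    stratification by seriousness, sex, age group and outcome with Wilson
    confidence intervals; MedDRA-style preferred-term / system-organ-class
    aggregation; time-to-onset and time-to-resolution summaries; Naranjo
    causality scoring; expectedness screening against a drug-label registry;
    and reporting odds ratio (ROR) disproportionality with Woolf 95%
    confidence intervals under a minimum-case rule. Includes a synthetic
    spontaneous-reporting dataset generator with injected drug-event signals
    of known strength so the whole pipeline is testable without access to a
    regulatory database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
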