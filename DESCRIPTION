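Package: hfdash
Title: Heart Failure EHR Phenotyping and Population-Health Dashboard Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based computable phenotyping of heart failure from
    EHR-style records: extraction of left ventricular ejection fraction
    (LVEF) mentions from free-text imaging reports, an imaging-quality
    evidence hierarchy, temporal selection logic yielding one effective
    LVEF per patient, classification into HFrEF / HFmrEF / HFpEF /
    unspecified phenotypes (with a legacy lowest-LVEF baseline algorithm
    for comparison), key-performance-indicator scoring aggregated at
    provider, facility, network and national levels, diagnostic-accuracy
    evaluation against gold labels, and a seeded synthetic-cohort
    generator emulating the documented failure modes of real clinical
    data sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
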