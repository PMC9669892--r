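Package: feverdq
Title: Completeness and Concordance Data-Quality Indicators for the FeverApp
    Fever-Diary Registry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for assessing the data quality of an
    ecological momentary assessment (EMA) fever-diary registry against
    structured physician reference records. Segments timestamped parental
    diary entries into fever episodes using a 48-hour gap rule, links child
    profiles between an app registry export and a pediatric office export by
    family code and demographics, pairs fever episodes across the two
    sources, and computes completeness (TMF-1042) and concordance (TMF-1002)
    data-quality indicators with exact Clopper-Pearson confidence intervals
    at family, profile, and episode levels. Includes a synthetic two-source
    cohort generator with known ground truth and a deterministic reference
    cohort built from the registry validation study's published marginal
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
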