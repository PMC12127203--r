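Package: pdxmpact
Title: Response Scoring and Biomarker Association for Preclinical PDX Basket Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores patient-derived xenograft (PDX) tumor-growth experiments for
    durability (relative median time to tumor quadrupling, EFSx4) and depth of
    response (group-level partial/complete regression), calls MGMT deficiency
    from MethyLight promoter-methylation (PMR), immunohistochemistry, and mRNA
    z-score inputs, and associates biomarker status with treatment response via
    a self-implemented two-sided Fisher exact test. Ships transcriptions of the
    preclinical NCI-MPACT PDX study's response and biomarker tables as fixtures,
    plus a synthetic cohort generator emulating staged, cyclically dosed,
    noisily measured tumor-volume time series so every pipeline stage is
    testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0), withr, tidyr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
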