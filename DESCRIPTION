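Package: petrad
Title: Sex-Specific PET Radiomics with Monte-Carlo Feature Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end amino-acid PET radiomics analysis pipeline for
    small clinical cohorts. Extracts an IBSI-conform set of 154 intensity,
    histogram and texture features from delineated lesions in both
    standardized-uptake-value (SUV) and tumour-to-background-ratio (TBR)
    configurations, collapses redundant features by absolute-Pearson
    correlation clustering with highest-variance representatives, builds
    aligned Monte-Carlo resampling plans holding out one patient per class,
    computes Tomek-link borderline and isolation-forest outlier diagnostics
    per fold, ranks features by per-fold R-squared occurrence, and confirms
    high-ranking features with Bonferroni-corrected Mann-Whitney tests.
    Ships a moment-targeted synthetic PET cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
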