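Package: pprsxe
Title: Pathway Polygenic Risk Score by Environment Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing interactions between polygenic risk scores
    (PRS) and environmental exposures in case-control studies, with an
    emphasis on pathway-restricted scores (pPRS). Provides a case-control
    cohort simulator with analytic effect-size calibration, a vectorised
    per-SNP marginal association scan, joint-model PRS weight estimation,
    pathway overrepresentation testing with false discovery rate control,
    centered logistic interaction models with likelihood-ratio tests,
    exposure odds-ratio profiling across score percentiles, and replicate
    machinery for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
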