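Package: putatex
Title: Synthetic Putamen ROI Cohorts and Histogram Texture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates seeded synthetic two-group cohorts of putamen-like
    2D regions of interest whose intensity distributions follow a
    skew-normal model calibrated to published group-level summary
    statistics, extracts first-order histogram texture features and the
    Katz fractal dimension from masked ROIs, runs distribution-gated
    two-sample comparisons (Shapiro-Wilk gate selecting Student's t or
    Mann-Whitney U; chi-square or Fisher for categoricals), and derives
    standardized texture-signature and percentile-shift profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
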