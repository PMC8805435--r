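Package: sftrisk
Title: Point-Based Metastasis Risk Models for Solitary Fibrous Tumor
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Point-based metastasis-risk stratification for solitary fibrous
    tumor (SFT): the Demicco three- and four-variable risk models and modified
    variants that replace the mitotic-frequency score with a Ki-67
    labeling-index score.  Includes hot-spot Ki-67 labeling-index
    quantification from labeled-nuclei field counts, metastasis-free-survival
    analysis implemented from first principles (Kaplan-Meier product-limit
    estimator with Greenwood variance and confidence bands, multi-group
    log-rank test), a Table-1-style cohort report with five-year
    metastasis-free survival per stratum, a seeded synthetic-cohort generator
    for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
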