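Package: urimeth
Title: Urinary DNA Methylation Biomarkers of Prostate Cancer Upgrading and Upstaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of urinary DNA methylation from quantitative
    methylation-specific PCR (qMSP) plate data via the delta-delta-Cq method,
    classification of prostate-cancer grade-group and stage migration between
    biopsy and radical prostatectomy with D'Amico-style pre- and post-operative
    risk groups, and evaluation of methylation markers (RARB, RASSF1, GSTP1),
    serum PSA and Partin nomogram values as predictors of upgrading, upstaging
    and risk-group increase: ROC analysis with DeLong inference, Youden-index
    threshold selection, prevalence-adjusted predictive values and odds ratios.
    Includes a synthetic-cohort generator with zero-inflated log-normal
    methylation levels and grade/stage transition structure, and a
    deterministic fixture cohort reproducing published cohort counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
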