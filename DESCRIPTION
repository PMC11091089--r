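Package: prsgxe
Title: Gene-Environment Interaction Analysis for Polygenic Risk Scores and
    Hormone Therapy in Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for joint and stratified analysis of a weighted polygenic
    risk score (PRS) and menopausal hormone therapy (MHT) exposure in
    case-control studies of colorectal cancer. Computes weighted allele-dosage
    risk scores and quartile categories, fits covariate-adjusted logistic
    models for a quartile-by-exposure cell grid, tests interaction on the
    multiplicative scale (likelihood ratio) and on the additive scale via the
    relative excess risk due to interaction (RERI) with Delta-method inference,
    and projects 30-year absolute risk by risk profile using external
    age-specific incidence and competing non-disease mortality rates with
    bootstrap confidence intervals. Includes a synthetic-data generator with
    known ground truth for calibration and parameter-recovery studies.
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
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
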