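Package: histosig
Title: Weighted Gene-Signature Scoring of Histologic Subtypes in Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted lepidic and solid gene signatures from
    subtype-labelled expression cohorts, computes per-sample L-scores and
    S-scores with a rank-based foreground/background enrichment statistic
    normalized against a permutation null, and runs the downstream
    prognostic, genomic-feature, drug-sensitivity and immunotherapy-response
    association analyses. Ships a synthetic-cohort generator so every stage
    of the pipeline is testable without external data.
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
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
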