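Package: chemoresponse
Title: Gene-Expression-Based Prediction of Chemotherapy Response with SVM-RFE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual patient response to chemotherapeutic drugs from
    tumor gene-expression profiles. Implements upper-quartile FPKM normalization
    of RNA-seq counts, zero-expression gene filtering, one-sample quantile
    normalization of microarray intensities against a reference distribution,
    linear max-margin classification with a drug-sensitivity scoring convention,
    staged recursive feature elimination with a minimal-feature tie-break,
    leave-one-out cross-validation, the CA-125 serum-marker response criterion,
    and combination-therapy outcome scoring with predictive-value summaries.
    Includes a seeded synthetic cohort generator so the full pipeline runs and is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
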