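Package: screeneval
Title: Evaluation of Docking Protocols and Scoring Functions for Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking structure-based virtual screening:
    docking-pose accuracy via heavy-atom RMSD against crystal conformations
    with an inclusive success threshold, scoring-function discrimination via
    ROC curves, pair-counting AUC with DeLong variance, confidence intervals
    and paired curve comparison, Youden-index optimal cutoffs, positive
    predictive value at fixed specificity, and enrichment factors at early
    fractions of the ranked library. Includes a binormal synthetic score
    generator with known ground-truth AUC, configurable ties and docking
    failures, so the whole pipeline runs without any proprietary docking
    engine, plus the published TbetaR1 re-docking and scoring benchmark
    tables used as worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    igraph,
    withr,
    stats,
    utils
Suggests:
    ChemmineR,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
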