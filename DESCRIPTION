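Package: mirpanel
Title: Serum miRNA Diagnostic Panel Construction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates linear diagnostic indices from serum
    microRNA microarray profiles in case-control cohorts. Implements
    internal-control normalization with a frozen reference level,
    geNorm-style control-stability assessment, robust expression
    filtering, Fisher linear discriminant analysis with greedy forward
    panel search driven by leave-one-out cross-validation, DeLong AUC
    inference for model-size selection, Youden-index recentring of the
    classification cutoff, and full validation reporting (subgroup
    sensitivity/specificity, predictive values at a screening
    prevalence, clustering and principal-component summaries). Ships a
    synthetic cohort generator with planted discriminative markers,
    including suppressor variables, so the whole pipeline is testable
    without access to any particular microarray data set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
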