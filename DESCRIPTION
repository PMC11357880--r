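Package: vnnsurv
Title: Pathway-Guided Visible Neural Networks for Survival Prediction from
    Binary Gene-Alteration Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and trains visible neural networks (VNNs) whose sparse
    connectivity mirrors a gene-to-pathway membership map and a pathway
    hierarchy, fitted to right-censored survival data with a Cox
    partial-likelihood loss. Provides Shapley-value attribution for input
    features and hidden pathway neurons, an altered-cases-only feature impact
    statistic, impact-ranked backward feature elimination, a genetic
    prognostic index (GPI) with three-level risk stratification, pairwise
    alteration co-occurrence and mutual-exclusivity analysis, and a synthetic
    cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
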