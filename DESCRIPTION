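Package: rbratio
Title: CCNE1/RB1 Ratio Biomarker Analyses for CDK4/6 Inhibitor Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse acquired resistance to CDK4/6 inhibitors
    (palbociclib) in hormone receptor-positive breast cancer models:
    intra-cell-line log2 fold-change normalization of expression profiles,
    the RBsig loss-of-Rb-function signature score (median/MAD
    standardization), a from-scratch weighted Kolmogorov-Smirnov gene set
    enrichment score with gene-permutation FDR, four-parameter logistic
    dose-response fitting with IC50 inversion, droplet digital PCR
    copy-number calling via Poisson occupancy, and evaluation of the
    CCNE1/RB1 expression ratio as a resistance and prognosis biomarker
    (correlation screens, ROC/AUC discrimination, Kaplan-Meier
    stratification). A synthetic-data module generates every input the
    pipeline consumes, with known ground truth, so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
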