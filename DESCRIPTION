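Package: plastiscore
Title: EMT, Metabolic and Immune-Checkpoint Signature Scoring with
    Pan-Dataset Meta-Analysis and Survival Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-sample scoring of epithelial-mesenchymal transition (EMT),
    metabolic and immune-checkpoint gene signatures on bulk and single-cell
    expression matrices: 76GS CDH1-correlation-weighted scores, signed
    two-sample Kolmogorov-Smirnov EMT scores, single-sample GSEA (ssGSEA)
    normalized enrichment scores, rank-AUC (AUCell-style) activities, and
    target-set activity scores. Includes curation of a PD-L1 co-expression
    signature across a pan-cancer compendium, volcano/quadrant correlation
    meta-analysis across datasets, Kaplan-Meier and Cox survival
    stratification by joint PD-L1/glycolysis status, and a synthetic-data
    generator with planted epithelial/hybrid/mesenchymal populations and
    coupled signature activities for end-to-end validation.
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
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
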