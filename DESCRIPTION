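Package: tlsmeta
Title: Tertiary Lymphoid Structure Signatures: Scoring, Meta-Analysis and
    De Novo Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating and discovering tertiary lymphoid structure
    (TLS) gene-expression signatures across immune-checkpoint-blockade (ICB)
    cohorts. Provides single-sample signature scoring (rank-based enrichment on
    z-scored expression, COX-IS, tumor mutational burden), per-cohort effect
    estimation (univariate Cox and logistic regression with a Firth fallback),
    fixed-effect and DerSimonian-Laird random-effects meta-analysis, de novo
    signature construction by a log-odds-ratio cutoff sweep, validation by
    response AUC with DeLong comparisons and survival association, and
    spot-level evaluation on spatial transcriptomics. A multi-cohort synthetic
    data generator with a planted TLS gene program supplies ground truth for
    every stage.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC
Config/testthat/edition: 3
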