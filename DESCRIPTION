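Package: sigforge
Title: Prognostic Gene-Signature Discovery and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derive and evaluate prognostic gene-expression signatures from
    gene-by-sample expression matrices and clinical follow-up data.
    Provides reference-relative z-scoring and binary alteration calling,
    Kaplan-Meier / log-rank / Cox survival statistics, prognostic-index risk
    stratification with minimum-p-value group maximization, quantile and
    best-cutoff splitting with Benjamini-Hochberg correction, greedy
    single-gene-removal (SGR) signature refinement, k-top-scoring-pairs
    (k-TSP) pair selection and classification, hypergeometric gene-set
    over-representation against GMT collections, and a synthetic-cohort
    generator with planted prognostic structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
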