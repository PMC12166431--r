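Package: deathmark
Title: Predicting Suppressors of Drug-Induced Cell-Death Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm target-prediction pipeline that ranks genes as candidate
    suppressors of a drug-induced cell-death pathway. One arm correlates
    drug-sensitivity AUCs, derived from dose-response viability curves, with
    cell-line gene expression and CRISPR gene-effect (essentiality) profiles.
    The other arm matches drug-response transcriptomic signatures against
    knockdown signatures via directional competitive gene-set enrichment and a
    rank-difference similarity score. Predictors are aggregated into ranked
    candidate lists by a best-predictors metric and by nearest-neighbour search
    in a UMAP embedding, with PubMed citation-count novelty filtering, a
    consensus-weight outlier filter for variant drug signatures, and preranked
    GSEA validation against pan-cancer sensitivity data. A synthetic-data
    generator with planted ground truth emulates every input class so the full
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    stringr,
    rlang,
    stats,
    utils,
    minpack.lm,
    pracma,
    uwot,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
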