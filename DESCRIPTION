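Package: mmpv
Title: Differential miRNA-mRNA Correlation Analysis Across Binary Clinical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects miRNA-mRNA paired variations (MMPVs): validated
    targeting pairs whose within-stratum Pearson correlation pattern
    differs between the two statuses of a binary biopathological feature
    (e.g. ER+/ER- breast tumours). Implements per-stratum correlation with
    Benjamini-Hochberg FDR, sign-change/fold-change classification and
    U/D/* pattern encoding, SAM-style permutation differential expression
    for DE-MMPV selection, cross-feature overlap counting, hypergeometric
    term enrichment against the targeting-pair background, and
    protein-interaction-network degree comparison, together with a
    seeded synthetic-data generator that gives every stage a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
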