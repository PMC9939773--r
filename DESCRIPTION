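Package: pscnet
Title: Differential lncRNA-mRNA Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for downstream transcriptomic
    screening of two-group RNA-seq designs such as case/control periosteal
    stem cell profiles: differential lncRNA and mRNA screening (FDR and
    fold-change criteria), hypergeometric gene-set over-representation with
    kappa-statistic clustering of redundant terms, lncRNA-mRNA Pearson
    co-expression network construction with connectivity-degree hub ranking,
    MCODE-style dense-module detection on interaction networks, genomic-window
    cis-target prediction, and a relative qRT-PCR (2^-ddCt) calculator. A
    fully parameterised synthetic-data generator plants known differential
    genes, correlation hubs, enriched terms and cis-proximal pairs so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
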