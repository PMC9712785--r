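Package: spongenet
Title: Construction and Analysis of circRNA-Centred ceRNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and analyse competing endogenous RNA (ceRNA)
    networks centred on circular RNAs. Provides differential-expression
    screening of circRNA, miRNA and mRNA tables under a fold-change and
    p-value rule, seed-match prediction of miRNA binding sites on circular
    and linear targets with a two-source consensus, assembly of
    circRNA-miRNA sponge networks with degree, betweenness and closeness
    centralities, median-multiple selection of key miRNAs, centrality-based
    ranking of hub circRNAs, direction-consistent circRNA-miRNA-mRNA triad
    assembly, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and 2^-ddCt relative quantification of
    qPCR validation data. A synthetic-data generator produces two-group
    negative-binomial counts with planted sponge triads and planted seed
    sites so that the whole pipeline can be exercised and benchmarked
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
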