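Package: mirphenet
Title: Rank-Based miRNA-Phenotype Association Networks for Post-Mortem
    Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens miRNA expression profiles against demographic,
    cognitive and neuropathological subject variables in small
    post-mortem cohorts using tie-corrected Spearman rank correlation
    (point-biserial for binary sex), builds signed phenotype-hub
    association networks with GEXF and GraphML export and a
    two-phase gravity layout, reproduces cohort-level group
    comparisons (Pearson chi-square, Kruskal-Wallis with Dunn's
    post hoc z-test), and scores predicted miRNA-mRNA target
    connectivity for an Alzheimer's-disease-related gene panel.
    Includes a negative-binomial cohort and count simulator with
    Gaussian-copula-planted correlations so the entire pipeline is
    testable without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
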