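Package: momnet
Title: Consensus Multi-Omic Association Networks for Dominance-Typed Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Momnet", "Maintainers", email = "maintainers@momnet.dev", role = c("aut", "cre"))
Description: Tools for cohort-scale association analysis between a
    vagino-cervical (or other lactobacilli-dominated) microbiome and
    companion omes: dominance-based community-state typing with centroid
    hierarchical ordering and the accompanying group statistics,
    cross-validated random-forest prediction power with permutation P
    values and Benjamini-Hochberg correction, between-ome effect sizes by
    forward-stepwise redundancy analysis (Ezekiel adjusted R-squared,
    Freedman-Lane permutation tests, double stopping), a three-learner
    (Spearman, random forest, L1-penalized regression) average-rank
    consensus association network with a Q-value gate, Edgington combined
    P-value replication across paired cohorts, and a seeded synthetic
    multi-omic cohort generator with planted ground truth for end-to-end
    validation. Profile tables are read and written in MetaPhlAn-style
    clade-string TSV; abundances are arcsine-square-root transformed for
    all linear analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
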