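Package: guildcraft
Title: Guild-Based (Co-Abundance Group) Analysis of Amplicon Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters amplicon sequence variants (ASVs) into co-abundance
    groups (CAGs, "guilds") by Ward clustering of a repeated-observations
    correlation distance computed on robust centered log-ratio (rCLR)
    transformed counts, with recursive PERMANOVA testing of dendrogram
    clades. Provides a genus-level comparator with a four-level
    data-reduction ledger, Procrustes/PROTEST information-loss scoring,
    Boruta-style random-forest marker selection with ROC validation and
    Spearman phenotype screening, empirical JTK_CYCLE detection of diurnal
    rhythms in time-course samples, and a synthetic community generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
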