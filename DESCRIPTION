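Package: conet
Title: Tissue-Specific Co-Expression Network Analysis and Hub-Gene Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds per-condition gene co-expression networks from expression
    matrices (quantile edge cutoff after low-expression filtering), detects
    co-expression clusters by random-walk community detection and selects key
    clusters by clustering coefficient, links clusters with a configuration-model
    observed/expected edge statistic, and compares regulatory and protein-protein
    interaction networks against co-expression using permutation nulls,
    co-regulator-count curves and Kolmogorov-Smirnov regulator selection.
    Scores transcription-factor influence on co-expression with a regression
    forest on co-binding features, projects co-expression onto metabolic
    reactions (maximum over enzyme pairs), clusters reactions hierarchically and
    ranks condition-specific and disease-deregulated clusters by differential
    Fisher Z co-expression, and prioritizes tissue-specific partners of a hub
    gene with quartile-stratified negative-binomial differential expression.
    Includes a synthetic multi-condition data generator with planted modules,
    transcription-factor effects, reaction maps, hub partners and
    negative-binomial counts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
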