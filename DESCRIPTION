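Package: fosnet
Title: Functional Coactivation Networks from Regional c-Fos Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds group-wise functional connectomes from regional
    immediate-early-gene (c-Fos) activity densities. Computes inter-regional
    Pearson correlation matrices, thresholds them into signed confidence
    networks at configurable cutoffs, scores nodes by degree and betweenness
    centrality, classifies composite hubs by percentile rules, detects
    communities by spectral modularity maximisation on the weighted
    correlation network, and profiles modular structure via complete-linkage
    hierarchical clustering with fractional-height tree cuts. Includes a
    factorial ANOVA stage with Bonferroni post hoc contrasts for per-region
    group statistics, and a synthetic cohort generator with planted
    covariance modules, hubs and group effects so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr
Config/testthat/edition: 3
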