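Package: comireg
Title: Context-Specific miRNA Regulation Networks for Drug Screening and
    Response Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the regulatory effect of each microRNA on each annotated
    gene set (a "CoMi index": a signed Welch-type contrast between the
    expression fold changes of the miRNA's target and non-target genes inside
    the set), discovers significant miRNA/gene-set patterns by hypergeometric
    overlap, assembles them into signed bipartite miRNA-to-term networks,
    ranks drug perturbation profiles by signature reversal with a
    Kolmogorov-Smirnov drug-screening-performance statistic and its
    permutation p-value, and predicts binary treatment response from
    per-sample CoMi features with under-sampled, cross-validated classifiers.
    Includes a seeded synthetic-data generator emulating paired tumor/normal
    cohorts, drug perturbation libraries and imbalanced patient cohorts, so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
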