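Package: pasway
Title: Pathway Activation Strength Profiling of Liver Regeneration Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracellular signaling pathway (ISP) activity from
    bulk RNA-seq count matrices using the pathway activation strength (PAS)
    statistic: the signed sum over pathway member genes of activator/repressor
    role times a beyond-tolerance-interval flag times the decimal log of the
    case-to-normal expression ratio. Includes a pathway knowledge-base format
    with per-gene activator/repressor roles, per-sample Gaussian and group
    Wilcoxon rank-sum significance machinery, cross-condition set comparisons
    (Venn partitions, Jaccard similarity, hierarchical clustering, PCA,
    correlation matrices, time profiles), miRNA target filtering and
    presence-pattern detection, rank-based single-sample gene-set enrichment
    scores, and a negative-binomial count simulator with planted pathway
    activations for end-to-end validation. Motivated by the study of
    accelerated liver regeneration after two-staged (ALPPS) hepatectomy in
    mouse surgical models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
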