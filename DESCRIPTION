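Package: lncluster
Title: Consensus Clustering of Tumor lncRNA Expression with
    Guilt-by-Association Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to stratify tumor cohorts from long non-coding RNA
    (lncRNA) expression and to characterize the resulting clusters.
    Implements consensus clustering with subsampled k-medoids
    partitions, consensus matrices and the proportion of ambiguous
    clustering (PAC) criterion for selecting the number of clusters;
    template-based guilt-by-association selection of per-cluster
    surrogate lncRNAs and of directly or inversely correlated
    protein-coding genes; hypergeometric gene-set over-representation;
    contingency-table association of clusters with clinical covariates;
    and Kaplan-Meier / log-rank survival comparisons. A synthetic cohort
    generator with planted cluster structure, marker genes, clinical
    covariates and survival endpoints makes the whole pipeline testable
    without access to controlled tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
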