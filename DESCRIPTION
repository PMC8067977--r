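Package: tecnet
Title: Co-Expression Network Analysis of Tumour Endothelial Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for weighted gene co-expression
    analysis of paired tumour versus non-tumour endothelial cell expression
    profiles. Provides two-Gaussian low-expression filtering, sample-network
    (zK) outlier removal, moderated differential expression for a paired 2x2
    design with subject blocking, single-sample gene-set scoring by a
    rank-based random-walk statistic, signed weighted network construction
    with biweight midcorrelation and topological overlap, iterative module
    detection with module-membership pruning, mixed-effects eigengene-trait
    association, hub-gene calling by intramodular connectivity, and
    hypergeometric GO enrichment with Wang semantic-similarity term
    reduction. A synthetic-data generator emulating the paired study design
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
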