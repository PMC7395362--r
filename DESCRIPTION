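Package: activeBreast
Title: Active and Inactive Transcriptome Phenotyping of Normal Breast Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies bulk RNA-seq transcriptomes of histologically normal
    breast tissue into a risk-associated Active versus Inactive phenotype and
    links the Active phenotype to mammary adipocyte biology. Provides
    sign-corrected gene-signature scoring on TPM values, IQR-gated selection of
    variably expressed classifier genes, unsupervised hierarchical clustering
    and phenotype label assignment, per-gene quantile-normalization batch
    integration with zero exclusion and reattachment, filtering of
    RNA-expressed cancer gene hotspot variant calls with per-sample mutation
    burden, post-processing of gene set enrichment report tables with an
    adipose name filter, group-comparison and correlation-matrix association
    statistics, and a synthetic cohort generator emulating the statistical
    structure of a two-batch normal breast study so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    ggplot2,
    jsonlite,
    methods,
    pheatmap,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
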