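Package: lncregnet
Title: Regulatory lncRNA Discovery from Two-Group Liver Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for prioritising liver loci and discovering
    regulatory long non-coding RNAs (lncRNAs) between two phenotype groups
    (for example cattle divergent in residual feed intake). Implements
    FPKM-based expression filtering, a negative-binomial Wald test for
    differential expression, regulatory impact factor (RIF1/RIF2) scoring of
    candidate lncRNA regulators, partial-correlation-and-information-theory
    (PCIT) co-expression edge selection, metabolite integration, natural
    antisense transcript and cis-interaction screening, and hub-lncRNA
    selection. Ships a synthetic-data generator with planted ground truth
    that emulates the statistical structure of such studies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
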