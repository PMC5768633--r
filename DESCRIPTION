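Package: lhcoex
Title: Learned-Helplessness lncRNA-mRNA Co-Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end workflow for profiling long non-coding RNA and
    mRNA regulation in the learned-helplessness mouse model of depression.
    Classifies mice into helpless (LH) and non-helpless (NLH) phenotypes by
    k-means clustering and linear discriminant analysis of shuttle-box escape
    behavior; performs Student's t-test differential expression across the
    four-group design (LH, NLH, Ctrl, HC) with multi-comparison exclusion
    filtering; builds lncRNA-mRNA co-expression networks from gene-level FPKM
    by Pearson-threshold edge filtering (r^2 >= 0.9, p < 0.01) with cis/trans
    classification by a 1000-kb genomic window; runs offline Fisher's-exact
    functional enrichment and lncRNA-bioprocess network construction; and
    implements 2^-ddCt qPCR relative quantification. A synthetic-data module
    generates all inputs with planted ground truth so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
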