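Package: antisensePairs
Title: Sense/Antisense Pair Cataloging and Fold-Change Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a catalog of gene / antisense non-coding transcript pairs
    from strand-aware genomic interval overlap (inner overlap join, opposite-
    strand filter, longest-ncRNA-per-gene resolution), computes two-condition
    negative-binomial differential expression (median-of-ratios normalization,
    method-of-moments dispersion, Wald test, Benjamini-Hochberg FDR), and
    quantifies the Pearson correlation of sense and antisense log2 fold-changes
    among pairs significant at a gene-level FDR threshold. Includes a synthetic
    data generator that plants a tunable correlation between sense and
    antisense effects in negative-binomial count matrices, so the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
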