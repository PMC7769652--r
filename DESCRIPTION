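Package: aaalnc
Title: lncRNA/mRNA Microarray Differential Expression and Regulatory
    Network Analysis for Abdominal Aortic Aneurysm Studies
Version: 0.1.0
Authors@R:
    person("AAA", "Transcriptomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a complete lncRNA/mRNA tissue
    microarray analysis for case-control designs such as abdominal aortic
    aneurysm (AAA) versus normal aorta: per-probe differential expression
    (unpaired pooled-variance t-test on log2 intensities, fold change as the
    absolute ratio of group mean intensities, Benjamini-Hochberg FDR),
    Fisher's exact and chi-square gene-set over-representation, six-way
    positional classification of lncRNA loci against a coding annotation,
    coding-noncoding coexpression networks from thresholded Pearson
    correlation, competing endogenous RNA (ceRNA) networks scored by a
    shared-miRNA hypergeometric test, 2^-ddCt qPCR relative quantification,
    and cohort summary-statistics tests. A seeded synthetic-data generator
    emulates the 5-versus-3 tissue design with planted ground truth so the
    whole pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    rtracklayer,
    optparse
Config/testthat/edition: 3
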