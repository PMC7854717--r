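Package: GenomicFabric
Title: Genomic Fabric Analysis of Replicated Multi-Condition Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the genomic fabric paradigm for replicated,
    spot-redundant gene expression experiments such as four-heart-chamber
    microarray profiling. Provides redundancy-aware average expression
    levels (AVE), chi-square corrected relative expression variability
    (REV), relative expression control of genes and pathways (REC, PREC),
    differential expression with per-gene adaptive fold-change cut-offs
    (CUT) and weighted pathway regulation (WPR), pairwise expression
    coordination and cross-condition synchrony classification, and gene
    commanding height (GCH) ranking for gene master regulator
    identification. Includes a synthetic-data generator with planted
    ground truth and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
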