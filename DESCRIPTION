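Package: gahd
Title: Genome-Wide Analysis of Histone Degradation from Pulse-Chase Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of histone degradation (GAHD) from
    pulse-chase sequencing of metabolically labeled histones. Calls enriched
    regions on binned coverage tracks, performs M-A (MAnorm-style) normalization
    between chase time points over common peaks, identifies degraded regions and
    proteasome-activator-dependent (PA200-dependent) degradation regions by
    genotype subtraction, classifies regions and genome areas by CpG methylation
    level from whole-genome bisulfite data, calls differentially expressed genes
    by the log2-ratio / diverge-probability rule, computes metagene and
    TSS-anchored signal profiles for histone marks and RNA polymerase II, and
    integrates the results per gene. A synthetic-data generator with planted
    ground truth drives end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
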