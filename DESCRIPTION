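Package: petromine
Title: Mining Hydrocarbon-Degradation Genes from Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a functional-gene mining
    pipeline for shotgun metagenomes of hydrocarbon-contaminated soils:
    removal of 454-style artificial replicate reads, six-frame translated
    local alignment of reads against reference protein panels with
    Karlin-Altschul E-values, two-stage recruitment (permissive E < 0.10
    recruitment followed by best-hit confirmation against a broad protein
    database with gene-family synonym rules), taxonomic aggregation at the
    phylum level (class for Proteobacteria), per-100-genome-equivalents and
    fixed-size subsampling normalizations with rank concordance,
    genome-size-corrected taxonomic profiles, and absolute qPCR
    quantification with lambda spike-in inhibition correction. Includes a
    synthetic-data generator that emulates pooled 454 pyrosequencing
    time-course datasets with planted gene fragments and known truth, so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
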