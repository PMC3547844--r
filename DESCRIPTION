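Package: clrscan
Title: Detection and Characterization of Centromere-Like Regions from
    Kinetochore ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies centromere-like regions (CLRs) in the budding
    yeast genome from multi-protein kinetochore ChIP-Seq data: a
    windowed enrichment scorer, a four-protein overlap caller with
    replicate reconciliation and ratio filters, randomization tests for
    genomic-context association (centromere proximity, ARS/tRNA/
    retrotransposon association, intergenic-length null), a sliding
    maximum-AT-content statistic, centromere-anchored signal
    aggregation with peak-width measurement, a 12-variable linear
    discriminant / principal component classification stage, and the
    accompanying assay statistics (qPCR fold enrichment, doubling
    times, fluctuation-analysis aggregation, Fisher's exact tests).
    Includes a synthetic-data generator emulating the study design so
    the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    MASS,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
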