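Package: reservoiR
Title: Promoter Occupancy, Permutation Enrichment and Reservoir Promoter
    Classification from ChIP-seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for promoter-centric integration of many DNA-binding-protein
    (DBP) ChIP-seq experiments measured in a single cell state. Builds
    replicate consensus peaks, binary promoter-by-DBP occupancy matrices,
    constrained genome-shuffle permutation enrichment at promoters and
    repeat families, TSS and element-centered coverage metaprofiles, TPM
    expression quantification, and the classification of "reservoir"
    promoters (heavily bound yet transcriptionally silent), including their
    ghost/zombie nascent-transcription split. Ships a synthetic-data
    generator with planted ground truth so the full pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
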