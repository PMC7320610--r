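Package: driverpass
Title: Driver Versus Passenger Classification of Somatic Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels somatic single-nucleotide variants as putative drivers
    (highly recurrent across tumours) or passengers (observed once) from a
    recurrence-annotated catalog, with window-matched negative selection to
    control for genomic location. Extracts genomic feature groups around each
    variant (conservation and uniqueness score tracks, GC content, local
    mutation frequency, proximity to gene features, k-mer spectrum, functional
    elements), trains a single-kernel classifier with train-fold
    standardization under leave-one-chromosome-out cross-validation, performs
    greedy forward feature-group selection, and supports cautious
    (confidence-thresholded) prediction. A seeded synthetic-data generator
    emulates genomes, annotations, score tracks and recurrence-structured
    variant catalogs so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
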