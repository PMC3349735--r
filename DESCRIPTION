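Package: bindmode
Title: Unique and Redundant Transcription Factor Binding Mode Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies ChIP-seq peak regions of a focal transcription factor
    (e.g. the ternary complex factor ELK1) as "uniquely" or "redundantly"
    bound relative to a second ETS-family factor (e.g. GABPA), and
    characterises the two binding modes: replicate-based confidence calling
    with an FDR filter, summit-based nearest-TSS assignment and promoter
    geometry, degenerate IUPAC word scanning with non-overlapping
    hexamer-derivative counting, composite ETS-SRF module detection under
    summit-distance and pair-distance constraints, k-means clustering of
    z-transformed knockdown-by-stimulus expression responses, and the
    association statistics tying binding mode to regulatory direction and
    functional category (2x2 tests, Monte-Carlo gene-list overlap z-scores,
    per-chromosome region-overlap permutation tests, hypergeometric gene-set
    enrichment). A fully parameterised synthetic-data generator emulates the
    statistical structure of the ChIP-seq and microarray experiments so that
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
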