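Package: SSRseqDesign
Title: Microsatellite Marker Design for Sequencing-Based Genotyping of
    Non-Invasive Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects perfect microsatellites (SSRs) in genome contigs under
    per-motif minimum repeat thresholds, filters candidate loci for
    short-amplicon SSR-Seq genotyping of degraded, non-invasively collected
    DNA, designs flanking primer pairs under length, melting-temperature,
    GC-content and spacing constraints, assembles compatible multiplex PCR
    sets under nearest-neighbor dimer and melting-temperature rules, and
    selects high-diversity mitochondrial barcode amplicons from sliding-window
    nucleotide diversity profiles. Includes synthetic-data generators (contigs
    with planted SSRs, alignments with diversity hotspots, primer panels with
    engineered dimer conflicts) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
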