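Package: txReadthrough
Title: Strand-Specific Meta-Gene Analysis of Transcriptional Read-Through
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies RNA polymerase II transcription termination failure
    from strand-specific RNA-seq coverage. Signal downstream of annotated
    transcript 3' ends is summed in fixed-width genomic windows, normalized
    per transcript to the signal in the terminal window of the gene body,
    and aggregated into meta-gene read-through profiles that can be compared
    between conditions with a bootstrap contrast. Includes coverage-based TPM
    filtering of analyzable transcripts, ingest of stranded bedGraph pairs or
    dUTP-protocol BAM alignments, a seeded simulator of stranded coverage
    with known read-through structure plus its analytic expectation oracle,
    and a reproducible configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
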