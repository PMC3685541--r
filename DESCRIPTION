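Package: txiso
Title: Assessment of Alternative Transcript Isoforms and In Silico Reporter Fusion Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a gene's annotated alternative
    transcripts plausibly encode distinct protein isoforms. Detects the
    structural mechanisms that generate alternative transcripts (alternative
    unique starting exons, nested transcript starts, alternative terminal
    exons, cassette exons, retained introns and splice-site shifts) from
    exon-chain comparison, grades the transcript-support evidence
    (EST/RT-PCR/ORFeome-clone alignments) as strong, weak or unsupported while
    flagging likely artifacts (5'-truncated cDNAs, unspliced genomic reads),
    and applies translation-based discount rules (premature termination codons
    and nonsense-mediated decay candidacy, blocking upstream ORFs, alternative
    reading frames) to classify each gene. Also performs in silico
    recombineering: seamless reporter insertions and single-base edits are
    applied to a locus and the expression of a translational reporter is
    predicted per transcript, supporting the design of minimal construct sets
    that distinguish transcripts. A synthetic-data module generates genomes,
    multi-transcript gene models realizing each mechanism, and transcript
    evidence with realistic artifact modes, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
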