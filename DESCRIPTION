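Package: nmdtrace
Title: Ribosome Footprint and 3' End Analysis of Nonsense-Mediated Decay
    Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise mRNA decay intermediates of
    nonsense-mediated decay (NMD) from ribosome profiling and 3' RACE data.
    Implements stop-codon-relative projection of aligned reads, UMI duplicate
    collapse, length-stratified positional tallies with a permutation z-score
    significance map for intermediate-sized footprints, stop-codon metagene
    profiles of normalised read density, gene-level cumulative distributions
    of read 3' ends with half-point ordering, reading-frame analysis
    downstream of stop codons, and +/-PNK library comparison to classify
    cleavage-site 3' end chemistry. A mechanistic simulator generates
    transcriptomes and reads under two competing cleavage models (direct
    A-site cleavage versus endonucleolytic cleavage followed by 3'>5'
    exosome trimming and trailing-ribosome run-on), including guanosine
    stalling of the exosome and an endonuclease-null mode, so every analysis
    stage can be exercised without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
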