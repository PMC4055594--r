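Package: swassembly
Title: Sliding-Window Greedy Assembly of Repeats and Nonrepeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Greedy seed-and-extend de novo assembly of short reads that
    separates repeat from nonrepeat regions by unique-read counts, filters
    overlap-count profiles with a rectangular sliding window to suppress
    sequencing bias, detects repeat boundaries from the filtered interval
    means, and estimates the copy number of every assembled repeat contig.
    Includes a repeat-structured paired-end read simulator (interspersed,
    tandem and compound repeat designs) and a repeat-aware evaluation suite
    (TRC, CNRC, NNC, CN-, Rep- and C-accuracy, N50/N90, E-size, genome
    coverage) based on Smith-Waterman alignment back to the reference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
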