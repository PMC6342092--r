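Package: dietbarcoder
Title: Diet Metabarcoding from Fecal COI Mini-Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable reimplementation of a fecal DNA metabarcoding
    workflow for bird-insect food webs: demultiplexing of index-tagged
    single-end amplicon reads, IUPAC-aware primer filtering, average-quality
    filtering, greedy de novo OTU clustering at a fixed identity threshold,
    rule-based taxonomic assignation against a local reference library, and
    the downstream diet and prey-availability statistics (rank-level
    identifiability, consumed-versus-available overlap, sequence-variant
    prevalence correlation, and a log-mass detection model for frass feeding
    trials). A synthetic-data module generates reference libraries, mock
    communities, error-bearing reads and feeding-trial tables with known
    ground truth so every stage is verifiable without sequencer output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
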