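Package: replifork
Title: Single-Molecule DNA Replication Dynamics from Nanopore BrdU Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of DNA replication dynamics on single nanopore
    sequencing reads carrying gradients of BrdU incorporation. Parses
    per-thymidine BrdU probability tracks (DNAscent detect format), computes
    windowed incorporation fractions, denoises their first derivative by
    total-variation regularized numerical differentiation, and calls
    replication fork direction, initiation and termination sites on each
    molecule. Provides permutation-based enrichment statistics for initiation
    site density (initiations per gigabase of mapped reads), relative-distance
    colocalization, replication fork directionality ensembles, fork
    co-directionality with transcription, and signal meta-profiles. Includes a
    forward simulator of asynchronous S-phase molecules under a sequential
    BrdU-addition labelling schedule with ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
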