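Package: itdscan
Title: Internal Tandem Duplication Discovery from Short-Read Sequencing Data
Version: 0.1.0
Authors@R:
    person("ITD", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Detects internal tandem duplications (ITDs) from short-read
    alignment files by mining unmapped and soft-clipped reads for duplicated
    kmer signatures, binning reads by repeat distance, confirming the
    duplication structure through fixed-length cycles in per-bin De Bruijn
    graphs (boolean adjacency-matrix exponentiation), assembling supporting
    reads with a greedy overlap-layout-consensus assembler, and annotating
    the collapsed contigs against a reference genome and capture targets.
    Includes a deterministic read simulator with implanted duplications for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    parallel,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
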