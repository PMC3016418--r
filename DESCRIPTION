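Package: pooldeconv
Title: Five-Dimensional BAC Clone Pool Design and Contig-Map Deconvolution
Version: 0.1.0
Authors@R:
    person("Physical Mapping", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and deconvolution of five-dimensional (5-D) BAC clone
    pooling experiments for high-throughput library screening. Constructs
    plate pools, row/column super-pools and per-library clone row/column
    sub-pools for multi-library 384-well plate collections; reads a minimal
    FPC-style contig map dialect with clone fingerprint band sets; and
    identifies the truly positive clones for each marker by exhaustive
    search over contigs using fingerprint spanning/inclusion/overlap
    relations and a discrimination score. Includes a seeded simulator of
    clone libraries, fingerprints, contigs and pool screening with
    injectable false-positive/false-negative pool hit rates, plus
    recall/precision evaluation against simulated truth and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
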