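Package: httscan
Title: Detection of Horizontal Transposable Element Transfer from
    Multi-Species TE Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers horizontal transposable element transfer (HTT) from
    targeted TE amplicon surveys spanning many host species. Clusters TE
    sequences into families by single linkage on pairwise alignment hits,
    computes Nei-Gojobori (1986) synonymous divergence (dS) between
    cross-species TE copies, tests each species pair against the 5%
    quantile of an MRCA-matched housekeeping-gene dS distribution chosen
    conservatively on a dated host phylogeny, counts the minimal number
    of transfer events on the host chronogram, and compares per-order
    event counts against a constrained network-permutation null model to
    flag transfer hotspots. Includes a seeded synthetic-data generator
    producing trees, reference dS panels, TE sequence sets with planted
    transfer events, and ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
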