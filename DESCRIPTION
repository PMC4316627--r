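Package: phyloroot
Title: Marker Screening, Supermatrix Construction and Outgroup Rooting
    for Deep Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for rooted phylogenomic analyses at the domain level:
    detection of conserved protein markers and taxonomic-consistency
    screening of their gene trees (class monophyly, horizontal gene
    transfer, paralogy, partial sequences, outgroup coverage),
    concatenation into partitioned supermatrices with missing-data
    accounting, desk-scale tree inference (corrected distances, neighbor
    joining, pruning-algorithm likelihood with discrete-gamma rate
    heterogeneity, nonparametric bootstrap), outgroup rooting with
    inter-domain stem-length statistics, and long-branch-attraction
    diagnostics based on with/without-outgroup placement experiments.
    Includes a gene-family simulator that plants HGT, paralogy, partial
    sequences and rate-accelerated clades with a ground-truth event log,
    so every screening and rooting procedure can be benchmarked against
    known events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
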