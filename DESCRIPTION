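Package: genusgap
Title: Whole-Genome Identity Metrics and AAI-Based Genus Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes average amino acid identity (AAI), percentage of
    conserved proteins (POCP) and fragmentation-based average nucleotide
    identity (ANIb) between prokaryotic genomes, detects discontinuities
    (gaps) in pairwise identity distributions, and assigns strains to
    genera by a dual-threshold rule anchored on type-species type strains.
    Also builds single-copy core-genome supermatrices (length and
    divergence filtering, codon-aware alignment, gap/invariant masking),
    provides Jukes-Cantor distances, neighbor-joining trees and
    Robinson-Foulds comparisons, fits the quadratic AAI-from-ANIb
    calibration and an extinction-anchored linear dating model, and ships
    a synthetic-clade simulator with known ortholog truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    phangorn,
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
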