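Package: mirevol
Title: Comparative Evolution of microRNA Repertoires Across Primates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of microRNA evolution across a
    primate-like clade: single-linkage homolog clustering of mature miRNA
    sequences, ortholog-group subdivision, mature-region variant detection
    with functional-region classification (seed, central, 3' supplementary,
    tail), precursor-hairpin structural conservation statistics (pairing-score
    minimum free energy, dinucleotide-shuffle z-scores, structure conservation
    index with covariance contribution), seed-shift detection, flank-anchored
    paralog presence/absence calling, and distance-based phylogenetics.
    Includes a synthetic-data generator that evolves miRNA families along a
    13-taxon primate-like tree with region-specific substitution rates,
    compensatory stem mutations, and lineage-specific duplication and
    deletion events, so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
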