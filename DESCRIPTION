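Package: plastchar
Title: Characterization of Quadripartite Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for characterizing annotated chloroplast (plastid)
    genomes: detection of the quadripartite LSC/SSC/IR layout and
    IR-junction gene distances, microsatellite (SSR) mining under
    MISA-style thresholds, maximal dispersed-repeat discovery (forward,
    palindromic, reverse, complement) with mismatches, per-gene and
    sliding-window nucleotide diversity (Pi), and a full codon-usage-bias
    suite (GC composition by codon position, RSCU, effective number of
    codons, neutrality and PR2 plot data, and optimal-codon
    identification from high/low-expression gene pools). A seeded
    synthetic-plastome generator with a ground-truth manifest makes every
    detector testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
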