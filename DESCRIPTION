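Package: mtlineage
Title: Matrilineal Analysis of Complete Human Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for matrilineal population analysis of
    complete human mitochondrial genomes: variant scoring against an
    rCRS-style reference in standard mtDNA nomenclature, Phylotree-style
    haplogroup classification, median-joining haplotype networks and
    mutation-weighted clade genealogies, rho-statistic molecular dating
    with heuristic standard errors, classical diversity statistics
    (haplotype and nucleotide diversity, Tajima's D), and population
    structure via distance-based AMOVA, pairwise PhiST and nonmetric
    multidimensional scaling. A built-in coalescent simulator generates
    mitogenome datasets with known genealogies, TMRCAs and island-model
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
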