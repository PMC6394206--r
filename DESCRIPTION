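Package: dupscan
Title: Tandem Gene Cluster Detection and Ks-Based Whole-Genome Duplication
    Inference for Plant Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analyses for annotated plant genome assemblies with an
    emphasis on tandem gene duplication and specialized-metabolism gene
    families. Detects physical (tandem) gene clusters under a two-rule
    chaining criterion (bounded intervening-gene count and inter-gene
    distance), filters gene-family candidates from similarity hits, finds
    telomere-repeat tracts and monomer tandem arrays (e.g. 5S rDNA), computes
    assembly contiguity statistics (N50/N90, size-class tables), estimates
    synonymous substitution rates (Nei-Gojobori 1986 with Jukes-Cantor
    correction) for paralog pairs, infers whole-genome duplication signatures
    by Gaussian-mixture modelling of Ks distributions corroborated with SiZer
    significance maps, and classifies expression divergence among tandem gene
    copies. A deterministic synthetic-genome generator with planted ground
    truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
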