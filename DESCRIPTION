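Package: salmap
Title: Sex-Specific SNP Linkage Maps and Assembly Integration for Salmonids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of high-density, sex-specific SNP linkage maps from
    nuclear-family pedigree genotypes and their integration with a physical
    genome assembly, modelled on the workflow used for the Atlantic salmon
    'ssalar01' array. Provides genotype quality control (Mendelian-error,
    minor-allele-frequency and segregation-distortion filters), two-point
    LOD-based linkage grouping with a plateau criterion for the clustering
    threshold, marker ordering by map-length minimisation, phased sex-specific
    centimorgan distances, physical placement of markers by exact flanking-
    sequence matching, anchoring of unplaced contigs to chromosomes, windowed
    recombination-rate (cM/Mb) landscapes folded by distance to the nearest
    telomere, and positional variant-effect classification against gene models.
    A self-consistent synthetic-data generator (genome, sex-specific crossover
    landscapes, pedigree, genotypes, marker flanks, gene models) with a known
    truth set makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
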