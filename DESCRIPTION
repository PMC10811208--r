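Package: herdscan
Title: Population-Genomic Scans for Crossbred Livestock Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for SNP genotype data from admixed livestock
    populations: diversity indices (Ho, He, Nei, PIC, MAF), sequential locus
    filtering and two-platform merging, windowed nucleotide diversity and
    Weir-Cockerham FST with Z-transformation and top-quantile intersection
    for selective-sweep scanning, neighbor-joining phylogenetics with
    bootstrap and outgroup rooting, genomic relationship matrix and PCA,
    binomial-likelihood admixture estimation with cross-validated choice of
    K, a diploid local-ancestry hidden Markov model, window-to-gene mapping
    with hypergeometric enrichment testing, and five-step core-SNP panel
    selection. Includes a Balding-Nichols synthetic-data generator for
    two-ancestry crossbred cohorts with known ground truth so every stage is
    verifiable by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
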