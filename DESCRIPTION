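Package: charrscan
Title: Population Genomics and Selection-Signature Scanning for
    Two-Population Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genomic comparison of two farmed fish
    populations from dense biallelic SNP data: genotype filtering and SNP
    density, observed heterozygosity, linkage-disequilibrium decay and
    LD-based historical effective population size, genomic relationships
    (Yang estimator) with PCA and LD pruning, sliding-window detection of
    runs of homozygosity and the genomic inbreeding coefficient F_ROH,
    a composite selection-signature scan combining windowed Weir-Cockerham
    F_ST with cross-population extended haplotype homozygosity (XP-EHH)
    through the de-correlated composite of multiple signals (DCMS),
    annotation of candidate sweep regions against GFF3 gene models with
    hypergeometric gene-set enrichment and Jaccard term similarity, and
    minimum-spanning-tree haplotype networks for aligned mitogenomes.
    A seeded two-population genotype simulator (Balding-Nichols allele
    frequencies, founder-haplotype mosaic linkage) makes every stage
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
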