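Package: tspscan
Title: Trans-Species Polymorphism Scans for Balancing Selection from
    Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for balancing selection in pooled-sequencing
    data. Detects cosmopolitan trans-species polymorphisms (SNPs that
    segregate in every focal population and in an outgroup species) from
    popoolation-style sync allele counts, tests their enrichment by
    genomic class, contrasts diversity statistics (pi, Watterson theta,
    Tajima's D, FST, nonsynonymous/synonymous heterozygosity) between
    TSP-bearing exons and other exons, and classifies candidate loci as
    under ancient versus recent balancing selection with a
    cophenetic-distance allele-tree statistic (CPD within minus between
    populations) assessed by permutation. A structured-coalescent
    simulator generates self-consistent synthetic datasets (FASTA, GFF3,
    sync, phased VCF) with implanted ancient balanced haplotype classes
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
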