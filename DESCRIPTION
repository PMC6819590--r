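Package: snpdiv
Title: Genetic Diversity and Structure of SNP-Genotyped Breeding Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much genetic diversity a set of related
    breeding lines holds and how it is partitioned among them. Reads SNP
    dosage panels from VCF or TSV, applies call-rate and minor-allele
    frequency quality control, computes the Yang et al. genomic relationship
    matrix and line-average kinships, and solves Eding's core-set problem for
    the line contributions that maximise conserved diversity, including
    leave-one-out unique diversity. Population structure is summarised by
    pairwise Weir-Cockerham Fst, principal components, and a neighbor-joining
    tree of lines; a permutation Fst-outlier scan with Benjamini-Hochberg
    false-discovery control flags candidate selection signatures and
    annotates them against gene intervals. A Balding-Nichols simulator
    generates panels of drifted parent lines plus an admixed merged line for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
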