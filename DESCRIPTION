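Package: PeRC
Title: Penalized Regression of Rare and Common Variants for Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-grouped penalized regression for quantitative-trait
    association with rare and common variants. Rare variants within each
    gene are collapsed into a single rescaled burden variable; all genes
    are then fit simultaneously under a combined group-lasso plus
    elastic-net penalty with minor-allele-frequency-derived weights. The
    objective is maximized by cyclic coordinate ascent with safeguarded
    Newton (CLG) updates, producing a sparsity path indexed by a single
    penalty scale kappa. Includes VCF genotype import, gene-interval
    group construction with overlap merging, covariate residualization
    of repeated phenotype measurements, and a synthetic-data generator
    with known causal structure for power and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Regression, GenomeWideAssociation, SNP, Genetics, Software
RoxygenNote: 7.3.3
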