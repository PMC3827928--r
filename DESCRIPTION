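Package: pedburden
Title: Pedigree-Based Rare-Variant Burden Association Testing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Family-based association tests for rare variants. Collapses rare
    variants in a gene or region into per-individual carrier indicators and
    tests affected against unaffected individuals while correcting for
    relatedness through a genetic relationship matrix, either estimated from
    genotyped markers or derived from pedigree structure. Provides the
    relatedness-corrected collapsing test, weighted-sum (WSS) and
    variable-threshold (VT) burden tests with permutation p-values, a
    corrected single-marker chi-squared test with min-p empirical p-values,
    joint iterative estimation of kinship and allele frequencies, a
    gene-dropping pedigree simulator with a forward Wright-Fisher founder
    pool and penetrance-model phenotype assignment, and an evaluation
    harness for empirical type I error and power under family study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'pedigreeSet.R'
    'pedGenotypes.R'
    'relatedness.R'
    'io.R'
    'kinship.R'
    'collapse.R'
    'assoc.R'
    'simulate.R'
    'evaluate.R'
    'pedburden-package.R'
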