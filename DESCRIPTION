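Package: mlgassoc
Title: Multilocus Genotype Association Analysis for Case-Control SNP Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for candidate-region case-control genetics
    built around multilocus genotypes (MLGs). Reads PLINK-style PED/MAP
    genotypes and covariate tables, applies standard variant quality control
    (minor allele frequency, call rate, exact Hardy-Weinberg equilibrium in
    controls), estimates pairwise linkage disequilibrium (D', r-squared) by
    two-locus EM from unphased genotypes, detects haplotype blocks with the
    solid-spine-of-LD rule, and tests block-wise MLGs for disease association
    with covariate-adjusted logistic regression and a global deviance
    likelihood-ratio test. Companion expression-side statistics cover
    delta-delta-Ct relative quantification of qPCR data, covariate-adjusted
    gene-gene regression with cell-type-marker correction, and exact
    small-sample nonparametric group tests. A synthetic-data module simulates
    block-structured genotype studies, expression tables and assay replicates
    with known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
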