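Package: snpgreml
Title: Genomic Heritability and Genetic Correlations via GREML with
    Relatedness Ceilings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of SNP-based heritability and genetic correlations
    for quantitative traits with genome-based restricted maximum likelihood
    (GREML). Provides SNP quality control (minor allele frequency,
    Hardy-Weinberg exact test, call rate, individual missingness),
    construction of the genomic relationship matrix (GRM) from allele
    dosages, reading and writing of the GCTA binary GRM format,
    relatedness-ceiling pruning of close relatives, univariate and
    bivariate average-information REML with delta-method standard errors,
    a gene-dropping simulator for pedigree-structured genotypes and
    correlated polygenic traits, and a sweep pipeline that re-estimates
    genetic parameters across a grid of relatedness ceilings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
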