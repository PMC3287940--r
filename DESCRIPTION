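Package: genotree
Title: Gene-Based Quantitative Trait Association with Genotype Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Gene-based association testing of quantitative traits against
    rare variants. Diploid genotypes are collapsed per gene into binary
    multilocus genotypes (carrier indicators), organised into a lexical
    genotype tree by splitting individuals site by site, and scored at every
    node with a z statistic for the node trait mean. The gene-level statistic
    S_k maximises the summed transformed node scores over sets of at most k
    pairwise disjoint nodes (an antichain) by dynamic programming, and
    significance is assessed by randomising trait labels within populations.
    The package also provides phenotype residualisation with covariates and
    principal-component loadings to control structure- and
    heterozygosity-driven confounding, and a structured-population simulator
    (Balding-Nichols allele frequencies, rare-variant spectrum, covariate and
    heterozygosity confound models) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
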