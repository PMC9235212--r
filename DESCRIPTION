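Package: ldhet
Title: Genomic Prediction and SNP-Heritability Under Linkage-Disequilibrium Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study and correct the impact of linkage-disequilibrium (LD)
    heterogeneity along the genome on genomic prediction (GBLUP) and
    SNP-heritability estimation (GREML). Implements the classical single-component
    genomic relationship matrix (GRM), the LD-weighted (LDAK-style) GRM obtained by
    solving a non-negative least-squares tagging system, and LD-stratified
    multi-component models (GREML-LDS) with one GRM per regional-LD level.
    Includes average-information REML with EM burn-in, GBLUP prediction for
    validation individuals, PLINK binary genotype input/output, quality-control
    filters, a haplotype-block genotype simulator with tunable regional LD
    heterogeneity, a quantitative-trait simulator with equal per-variant
    heritability contributions, and an experiment driver for replicated
    scenario grids, cross-validation and model comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
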