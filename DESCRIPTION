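Package: EcotypeScan
Title: Population-Genomic Scans for Divergence Between Resident and
    Migratory Ecotype Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for contrasting resident and anadromous (migratory)
    population pairs with biallelic SNP panels: genotype quality control
    with Hardy-Weinberg exact tests and Benjamini-Yekutieli false-discovery
    control, Weir-Cockerham F_ST with bootstrap confidence intervals,
    heterozygosity-conditioned F_ST outlier scans against a simulated
    neutral null, linkage-disequilibrium effective population size,
    kinship-corrected mixed-model association for a binary life-history
    phenotype, and random-forest backward purging on residualized
    genotypes. Includes a synthetic-data generator emulating strongly
    differentiated and panmictic ecotype pairs, plus genepop and tabular
    genotype input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
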