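Package: popkit
Title: Population Structure, Relatedness and Reference-Panel Evaluation for
    Harmonized Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetics core of a harmonized
    whole-genome cohort analysis: genotype QC (allele-frequency, missingness,
    exact Hardy-Weinberg and excess-heterozygosity filters, windowed LD
    pruning), KING-robust kinship with relationship classification and
    maximal-independent-set extraction of unrelated samples, HWE-normalized
    PCA with projection of external samples and random-forest ancestry label
    transfer, Weir-Cockerham F_ST and f2 doubleton sharing against geographic
    distance with migration waypoints (Pearson and Mantel tests), cross-dataset
    allele-count comparison in minor-allele-frequency bins, and evaluation of
    phasing (switch error rate) and imputation (aggregate r squared by MAF
    bin). Includes a seeded Balding-Nichols simulator with pedigrees,
    geography, phased haplotypes and imputation-noise models so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
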