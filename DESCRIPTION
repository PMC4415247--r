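Package: immunopop
Title: Population Immunogenetics of Hyperpolymorphic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-level analyses of hyperpolymorphic immune
    loci such as MHC class II genes alongside neutral microsatellite panels.
    Provides clone-based genotype validation, per-population polymorphism
    statistics (heterozygosity, haplotype diversity, nucleotide diversity,
    rarefaction allelic richness with permutation confidence intervals,
    exact Hardy-Weinberg and genotypic linkage-disequilibrium tests),
    differentiation estimators robust to high allelic diversity (Hedrick's
    G'ST and Jost's D), Mantel isolation-by-distance tests, codon-level
    selection analyses (Nei-Gojobori Z test, counting-based per-site
    selection with recombination-aware segment trees, single-breakpoint
    detection by small-sample AIC, and a multi-model consensus rule),
    physicochemical supertype clustering of alleles, and seeded generators
    of synthetic data sets with the population structure these analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    ggplot2,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
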