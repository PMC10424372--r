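Package: introgressr
Title: Archaic Introgression Calling and Case-Control Association for
    Haplotype Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies Neandertal-introgressed single nucleotide
    polymorphisms (aSNPs) in phased modern haplotype panels and tests them
    for disease association. Candidate archaic alleles are selected by
    allele sharing with an archaic reference genome (homozygous in the
    archaic individual, absent from an African outgroup, segregating in at
    least one non-African population) and then tested against incomplete
    lineage sorting with a recombination-rate-aware segment-length model
    corrected by the Benjamini-Hochberg method. The package also provides
    pre-association quality control (variant and sample call rate,
    heterozygosity outliers, PLINK-style relatedness, principal-component
    outliers, Hardy-Weinberg equilibrium, imputation quality),
    covariate-adjusted logistic association with LD pruning, independent
    test counting and Bonferroni thresholds, genomic inflation
    diagnostics, cross-study effect-direction concordance, and a
    synthetic-data generator that produces admixed panels with known
    introgressed and lineage-sorting tracts plus case-control phenotypes
    so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
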