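Package: melanoscan
Title: Selection Scans and Quantitative-Trait Association for Skin
    Pigmentation Candidate Genes
Version: 0.1.0
Authors@R:
    person("Melanoscan", "Developers", email = "melanoscan@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene studies of skin
    pigmentation in structured human populations. Provides genome-scan
    statistics for positive selection (locus-specific branch lengths from
    pairwise FST, lnRH heterozygosity ratios, Tajima's D in sliding
    windows, and a long-range haplotype test based on relative extended
    haplotype homozygosity with a gamma null and false discovery rate
    control), exact Hardy-Weinberg testing, EM-based two-locus haplotype
    frequency estimation and r-squared linkage disequilibrium, additive
    and unconstrained linear-model association of SNP genotypes with a
    quantitative melanin index, analytic and simulation-based power
    calculations, and seeded synthetic-data generators (Hardy-Weinberg
    cohorts, Wahlund mixtures, Balding-Nichols allele-frequency panels,
    and forward Wright-Fisher selective sweeps) that exercise the whole
    pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
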