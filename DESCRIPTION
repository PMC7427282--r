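Package: vectorpop
Title: Population-Genetic Analysis of Forest and Village Mosquito Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-based population genetics of Aedes aegypti
    cohorts sampled across forest, peridomestic and domestic habitats:
    genotype input/output (VCF and tabular multi-allelic formats), a
    PLINK-style six-stage quality-control filter cascade (missingness,
    exact Hardy-Weinberg tests, variance-inflation-factor LD pruning,
    minor-allele frequency, heterozygosity outliers), Loiselle pairwise
    kinship with sibling-group detection and deduplication, expected and
    observed heterozygosity, rarefied allelic and private allelic richness,
    Weir-Cockerham Fst with permutation differentiation tests and a
    sliding-window genome scan, Mantel tests and distance-residual
    kinship comparisons across habitat categories with resampled ANOVA,
    and a Balding-Nichols two-deme cohort simulator with known ground
    truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    vcfR,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
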