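Package: mrtriad
Title: Genotype-Biomarker-Disease Triad Analysis with Bayesian Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for triangular genetic-epidemiology
    studies in which genetic variants at a regulatory locus perturb plasma
    biomarker concentrations (complement factor H and factor H-related protein 1)
    which in turn may alter disease risk (age-related macular degeneration).
    Provides a multi-cohort synthetic-data generator with haplotype-level
    linkage disequilibrium, pedigree-structured polygenic effects and a common
    deletion polymorphism; per-locus association scans including a polygenic
    mixed-model score test for related individuals; kinship-based REML
    heritability and single-locus variance partitioning; EM estimation of
    two-locus haplotype frequencies and LD statistics from unphased genotypes;
    relative-quantification copy-number calling from qPCR Ct values;
    observational case-control statistics; and a Bayesian instrumental-variable
    (Mendelian randomization) model that combines cohorts with different
    measurement layers, treats unmeasured biomarkers as latent, imputes missing
    genotypes and adjusts for pleiotropic coding variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    rjags,
    knitr
Config/testthat/edition: 3
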