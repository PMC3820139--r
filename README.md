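# mrtriad

Genotype → biomarker → disease triad analysis with Bayesian Mendelian
randomization, on fully synthetic cohorts.

## The problem

Common variants in the regulators-of-complement-activation region
(chromosome 1q32) have large effects on two plasma proteins — complement
factor H (CFH) and factor H-related protein 1 (CFHR1) — and are among the
strongest genetic risk factors for age-related macular degeneration (AMD).
An intronic regulatory variant raises plasma CFH; it is in tight LD
(r² ≈ 0.84) with a common ~86 kb deletion (CNP147) that removes
*CFHR3*/*CFHR1* and lowers plasma CFHR1; and coding variants (Y402H, I62V)
alter CFH function without large concentration effects. Observationally,
AMD cases have *lower* measured CFHR1 than controls even though their
genotypes predict higher values — a classic signature of reverse causation.
Disentangling which biomarker, if either, causally drives disease requires
an instrumental-variable ("Mendelian randomization") analysis that combines
cohorts with different measurement layers and allows for pleiotropic coding
variants.

`mrtriad` re-implements that entire analysis chain as a tested R package,
for biostatisticians who want to study, extend or stress-test the design.
Since the original cohorts are private, a first-class synthetic-data module
generates multi-cohort bundles with the same statistical structure —
haplotype-level LD, pedigree relatedness, covariates, assay noise, disease
ascertainment, post-onset shifts — with every true parameter recorded, so
each stage is validated by parameter recovery.

## What is inside

| Stage | Functions |
|---|---|
| Haplotype/LD model and gene dropping | `build_haplotype_model`, `simulate_genotypes`, `simulate_pedigrees` |
| Biomarker + disease generator, cohort assembly | `simulate_biomarkers`, `simulate_disease`, `apply_onset_shift`, `assemble_cohorts` |
| Association scans (OLS, polygenic mmscore, conditional) | `fit_additive_linear`, `fit_polygenic_null`, `mmscore_scan`, `conditional_scan` |
| Heritability / variance partition (REML on kinship) | `estimate_h2`, `snp_variance_partition` |
| Two-locus LD from unphased genotypes (EM) | `em_haplotype_freqs`, `dosage_correlation` |
| qPCR ΔΔCt copy-number calling | `simulate_qpcr_plate`, `delta_delta_ct`, `call_copy_number` |
| Case-control statistics and power | `compare_means`, `logistic_or_per_sd`, `two_sample_power`, `partial_correlation` |
| Bayesian instrumental-variable model | `iv_model_spec`, `build_iv_model`, `run_mcmc`, `summarize_posterior`, `observational_vs_causal_report` |
| IO (VCF/TSV/YAML/JSON) and orchestration | `read_genotypes`, `write_vcf`, `read_config_yaml`, `run_pipeline` |

The core model is the joint Bayesian system

```
(X1, X2) = alpha_c + B G + C Z + eps,    eps ~ N2(0, Sigma)
logit P(D = 1) = gamma_c + theta' X_std + delta' G_pleio + phi' Z
```

with latent exposures for genotype-only cohorts, free cohort intercepts for
case-control ascertainment, missing genotypes sampled from haplotype-informed
priors, and normal/half-normal/uniform weakly informative priors, sampled by
an adaptive Metropolis-within-Gibbs scheme. `theta` is the causal log odds
ratio per 1 SD of biomarker; `delta` are direct (pleiotropic) per-allele
effects of the coding variants.

## Worked example

```r
library(mrtriad)

b <- assemble_cohorts(cohort_config(), seed = 42)   # four-cohort bundle
pop <- b$cohorts$population

# additive association of the index SNP with plasma CFH (age+sex+BMI adjusted)
fit_additive_linear(pop$biomarkers$cfh, pop$dosages[, "rs6677604"],
                    pop$covariates)
#>   locus  beta    se         p      r var_explained var_explained_adj   n
#> 1 locus 24.67 3.056 2.003e-15 0.2495       0.06205           0.06235 986

# narrow-sense heritability from the pedigree kinship
estimate_h2(pop$biomarkers$cfh, pop$covariates, pop$kinship)
#>      h2  se_h2 sigma2_g sigma2_e boundary
#> 1 0.336 0.0764     1228     2431 FALSE

# LD between the index SNP and the deletion, from unphased dosages
em_haplotype_freqs(pop$dosages[, "rs6677604"], pop$dosages[, "CNP147"])
#> Two-locus LD (n = 966): r2 = 0.7989, D' = 0.9014, D = 0.16430 (8 EM iterations)
```

The per-allele estimate (24.7 ± 3.1 µg/ml) recovers the generating effect of
25.6 µg/ml; the single-cohort heritability estimate (0.34 ± 0.08) sits below
its generating value of 0.46, as expected for one mixed family/singleton
cohort of this size — the sibship design used by the recovery studies is
much more informative. The EM r² of 0.80 estimates the generating 0.84 at
n ≈ 1000 (0.84 ± 0.02 is recovered at 100,000 draws).

Fitting the causal model on the default three-cohort bundle:

```r
model <- build_iv_model(b, cohorts = c("population", "casecontrol_bio",
                                       "casecontrol_geno"))
fit <- run_mcmc(model, n_chains = 4, n_iter = 2000, n_warmup = 1000, seed = 1)
summarize_posterior(fit)        # posterior means, 95% CrIs, R-hat, ESS
```

The generator's causal odds ratio per SD of CFH is 0.52 and its CFHR1
effect is null; the posterior recovers both (see `tests/testthat/` and the
methods vignette for the full recovery studies).

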