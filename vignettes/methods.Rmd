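---
title: "Models and methods in mrtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mrtriad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mrtriad` studies a triangle of relationships that recurs in molecular
epidemiology: genetic variants at a locus perturb the plasma concentration of
a biomarker, and the biomarker may in turn alter disease risk. The concrete
system is the regulators-of-complement-activation region on chromosome 1q32:
a regulatory variant in *CFH* raises plasma complement factor H (CFH) and,
through tight linkage disequilibrium with a common ~86 kb deletion removing
*CFHR3*/*CFHR1* (CNP147), lowers plasma factor H-related protein 1 (CFHR1);
both proteins have been linked to age-related macular degeneration (AMD).
Because real cohorts of this design are private, the package pairs every
analysis stage with a synthetic-data generator whose true parameters are
recorded, so each method is validated by parameter recovery.

## The synthetic cohorts

**Haplotype model.** Loci are biallelic (the deletion is treated as an
allele on haplotypes, so deletion dosage is the count of deletion-bearing
haplotypes). Multi-locus haplotypes are factorized through the index
regulatory SNP: given the index allele, the other loci are conditionally
independent, each coupled to the index with coupling coefficient
$D = r\sqrt{p_A q_A p_B q_B}$ chosen to hit a requested pairwise $r^2$
exactly. This realizes the pairwise LD the analyses need (deletion
$r^2 = 0.84$, coding variants $r^2 = 0.16$ and $0.04$ to the index SNP)
without asserting anything about higher-order structure; requested $r^2$
values beyond the frequency-feasibility bound
$|D| \le \min(p_A q_B, q_A p_B)$ raise an error that names the attainable
maximum. Genotypes are gene-dropped: founders draw two independent
haplotypes (Hardy-Weinberg), offspring inherit one haplotype per parent,
with no recombination across this sub-megabase block.

**Pedigrees and polygenic background.** Cohorts mix nuclear families and
singletons. A polygenic component with covariance $\sigma^2_{poly} K$ (where
$K = 2\Phi$ is the additive relationship matrix) is sampled by the founder /
midparent / segregation-noise recursion, which reproduces $\sigma^2_{poly}K$
exactly for non-inbred pedigrees. Heritability cohorts use 251 sibships of
four phenotyped siblings (unphenotyped parents used only for gene dropping),
n = 1004.

**Biomarkers.** Each trait is intercept + per-allele effects + covariate
effects (age, sex, BMI) + polygenic + environmental noise. Two preset
calibrations resolve an internal tension in the published numbers: the
printed per-allele effect (25.6 ug/ml on CFH at MAF 0.25, total SD 62)
implies a locus variance share of about 6%, while the printed share is 26%.
The `effect_match` preset fixes the per-allele effect; `variance_match`
fixes the variance share ($0.26$ of covariate-adjusted variance for CFH,
$0.40$ for CFHR1) and derives the effect. In both, locus + polygenic
variance equals the trait heritability (0.46 CFH, 0.69 CFHR1), so the locus
share of additive variance is about 57-58% under `variance_match`. CFHR1 is
plate-relative (unitless); its mean is 0.93 and its total SD (0.248) is set
so that the deletion effect that reproduces the index-SNP slope of $-0.23$
per allele also reproduces the deletion-dosage correlation of $-0.62$.
Covariate distributions (age uniform 40-90, sex Bernoulli(0.5), BMI normal
27/4) and their small effects are declared defaults, present only so the
adjustment code has something to adjust for.

**Disease.** $\mathrm{logit}\,P(D=1) = \gamma_0 + \theta^\top x_{std} +
\delta^\top g + \phi^\top z$ with the latent (pre-onset) biomarkers
standardized by the generator's analytic SD, pleiotropy dosages centered,
and baseline prevalence 0.10 (a plausible figure for advanced AMD in an
elderly sampling frame). The `causal` preset uses the multivariate truth
($\theta_{CFH} = \log 0.52$, $\theta_{CFHR1} = 0$, direct coding-variant
log-ORs $\log 1.69$, $\log 0.47$, $\log 0.96$). The `observational` preset
instead solves, by numerical integration of the logistic-normal model, for
the single slope on CFH that makes the expected case-control gap equal
15.7 ug/ml. A post-onset shift can be applied to measured CFHR1 of affected
individuals; its magnitude is solved from the discriminant relation (the
induced conditional logistic slope per unit equals shift / residual
variance) so that the adjusted odds ratio per SD equals 0.72. These
calibrations consume only printed study values and closed-form/quadrature
algebra, never test outcomes.

**Cohort layout.** One shared haplotype model feeds four cohorts: a related
population cohort with biomarkers (n = 1004), an unrelated replication
population (n = 500), a case-control series with biomarkers (382/201, with
242 advanced cases flagged; case-control sampling is without replacement
from a simulated population at prevalence 0.10), and a genotype-only
case-control series (874/418). Genotypes are missing completely at random
at 2% by default. The full generating truth, including calibrated
constants, is stored in the bundle and serializable to JSON.

What the generator does *not* emulate: assay floor/ceiling effects,
genotyping error, population stratification, age-dependent effect sizes,
higher-order LD. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated model, not robustness to those
real-data complications.

## Analysis stages

**Association scan.** Per-locus ordinary least squares of trait on dosage
plus covariates; variance explained is reported both against raw and
covariate-adjusted trait variance, because published "variance explained"
figures are ambiguous between the two. For related cohorts, a polygenic
null model is fitted once by REML — eigendecomposition of $K$, profiled
restricted likelihood over $h^2$ — and each locus is tested with the
mixed-model score statistic $T = (\tilde g^\top V^{-1} r)^2 / (\tilde
g^\top V^{-1}\tilde g)$ with $V = \hat\sigma^2_g K + \hat\sigma^2_e I$,
covariate-adjusted dosage $\tilde g$, and null GLS residuals $r$; the
reported effect is the one-step estimate $\tilde g^\top V^{-1} r / \tilde
g^\top V^{-1}\tilde g$. Conditional scans append an adjustment locus to the
covariates and drop it from the output. Missing dosages are mean-imputed
for score tests (rates are low by design) and dropped pairwise elsewhere.

**Heritability and variance partition.** `estimate_h2()` is the same REML
machinery; its SE comes from finite-difference curvature of the restricted
log-likelihood (the original analysis used SOLAR, whose exact SE method is
unspecified; likelihood curvature is the standard equivalent). Boundary
estimates are flagged. `snp_variance_partition()` adds the locus as a fixed
effect and decomposes covariate-adjusted variance into locus
($\hat\beta^2\mathrm{Var}(g)$), polygenic and environmental shares, which
sum to one by construction.

**Linkage disequilibrium.** Two-locus haplotype frequencies from unphased
dosages by EM over the 3x3 genotype table (only double heterozygotes are
phase-ambiguous), initialized at linkage equilibrium, converging when the
log-likelihood gains less than 1e-10 (monotonicity is asserted every
iteration). $D'$ and $r^2$ follow from the fitted table; the plain dosage
correlation is also available since published $r^2$ values may come from
either estimator.

**qPCR copy-number calling.** The standard $2^{-\Delta\Delta C_t}$ method
against a two-copy calibrator: triplicates averaged after discarding wells
more than 1.5 cycles from the triplicate median, no-amplification sentinels
mapped to RQ 0, failed references flagged and excluded. Calls round
$2\,RQ$ to {0, 1, 2} with half-up boundaries at 0.5 and 1.5; estimates
above 2.5 are flagged out-of-range. Amplification efficiency is a config
knob, defaulting to exact doubling.

**Observational case-control statistics.** Pooled-variance t-test by
default (Welch by flag, matching the era-typical primary analysis),
covariate-adjusted comparison via the disease coefficient in a linear
model, logistic odds ratios per sample SD with Wald intervals, partial
correlations via covariate residuals with Fisher-z intervals, and the
two-sided normal-approximation power formula. That formula reproduces the
31-42% power band of the three cited small studies at a 0.27 SD difference;
the original report's own 84% figure is not exactly reproducible under any
single stated convention (the same formula gives about 87% at 382/201), so
it is documented here rather than targeted.

## The Bayesian instrumental-variable model

The causal question — does plasma CFH (or CFHR1) causally alter disease
risk, or is the association an artifact of confounding or reverse causation
— is answered by a joint multi-cohort model using genotypes as instruments:

* exposure equations: $(X_1, X_2) = \alpha_c + B G + C Z + \epsilon$,
  $\epsilon \sim N_2(0, \Sigma)$ on the standardized biomarker scale;
* outcome equation: $\mathrm{logit}\,P(D=1) = \gamma_c + \theta^\top
  X_{std} + \delta^\top G_{pleio} + \phi^\top Z$.

Non-coding variants (the index SNP and the deletion) are instruments:
they may affect disease only through the biomarkers. The three coding
variants get direct paths $\delta$ (pleiotropy covariates), because a
protein-sequence change can act on disease without changing concentration;
omitting them demonstrably biases $\theta$ through LD with the instruments
(a property test exercises this). The model assumes no unmodelled
confounding of genotype and disease and no developmental compensation.

Design choices worth recording:

* **Cohort asymmetry.** Exposure-only cohorts contribute only the exposure
  equations; outcome-only cohorts carry a latent biomarker pair per
  individual, integrated by MCMC; exposure+outcome cohorts contribute both.
  Each case-control cohort has a free intercept $\gamma_c$, the standard
  prospective-logistic treatment of retrospective sampling.
* **Ascertainment and the exposure equations.** The Gaussian exposure
  likelihood is fitted only to population cohorts and unaffected controls.
  Including case-enriched rows tilts the exposure residual distribution
  (cases are selected partly on low CFH) and inflates $|\theta|$; the logistic
  outcome part, by contrast, remains valid under outcome-dependent sampling
  with free intercepts, so measured case biomarkers still inform
  $P(D\mid X)$. When a post-onset shift is suspected, the
  `use_case_biomarkers = FALSE` switch removes case biomarkers from the
  likelihood entirely and the causal estimate rests on the genotype
  channel; this is the configuration used for the
  observational-versus-causal dissociation analysis.
* **One residual covariance.** $\Sigma$ (two SDs and a correlation) is
  shared across cohorts rather than cohort-specific: the generator has a
  single assay mechanism, and a shared $\Sigma$ keeps the
  cross-cohort standardization coherent. The posterior of the residual
  correlation doubles as the assay cross-reactivity check (it covers zero
  when the generator's assay correlation is zero).
* **Missing genotypes** are sampled parameters. Entries at the coupled
  instrument pair use conditionals from EM-fitted two-locus haplotype
  frequencies — propagating phase/LD uncertainty without explicit phasing —
  and other loci use marginal Hardy-Weinberg priors.
* **Priors.** Normal(0, 2^2) on standardized coefficients and log-ORs,
  half-normal(0, 3) on residual SDs (standardized scale), uniform(-1, 1) on
  the residual correlation: weakly informative on every scale that occurs.
* **Sampler.** Metropolis-within-Gibbs: a conjugate matrix-normal Gibbs
  draw for the exposure coefficients; adaptive random-walk Metropolis for
  the covariance block, the outcome coefficients (componentwise, target
  acceptance 0.44) and the latent exposure pairs (vectorized over
  individuals, target 0.35); categorical Gibbs for missing genotypes. Step
  sizes adapt during warmup only, so post-warmup draws form a fixed Markov
  chain. Summaries report split R-hat and effective sample size per
  parameter, and a warning flag is raised if any causal or direct effect
  has R-hat above 1.05. Posterior odds-ratio intervals are exponentials of
  log-scale quantiles.

Chain-length defaults are 4 chains of 1000 warmup + 2000 draws; the
bundled recovery studies use 4 x (1000 + 1100) per fit, which holds R-hat
near 1.0 for the headline parameters on the ~2,700-person bundle. The
identity-link (`gaussian`) outcome variant exists to validate the sampler
against two-stage least squares on fully observed data; the tests require
agreement within Monte-Carlo error.

## Numerical conventions and edge cases

Infeasible LD targets, monomorphic loci, rank-deficient designs,
identity-kinship REML (non-identifiable), separation in logistic fits,
empty case-control groups and malformed input files all raise typed errors
rather than returning numbers. EM ties are broken by the
linkage-equilibrium initialization basin. REML constrains $h^2$ to [0, 1]
and reports exact-boundary fits with a flag and an unreliable-SE caveat.
All randomness flows from one master seed through named child streams
(`child_seed`), so every stage is independently reproducible and a full
pipeline re-run is bit-identical.

## Problem sizes used in the bundled studies

Recovery studies are sized to the original cohorts: n = 1004 for the
population and sibship analyses (25-50 seeds averaged), 382/201 (242
advanced) and 874/418 for the case-control series, 100,000 haplotype draws
for LD recovery, and 10 replicate fits of the three-cohort
instrumental-variable bundle. These sizes make the recovery targets'
Monte-Carlo error small relative to their tolerances while keeping a full
run in minutes on one core.

## Known limitations

The latent-exposure random-walk updates mix slowly when a model is
identified almost entirely through genotype-only cohorts; with the default
multi-cohort bundle (which always contains a measured exposure+outcome
cohort) this shows up only as moderate autocorrelation. Posterior means of
weakly identified causal effects sit slightly away from the mode because
the marginal mapping from causal slope to genotype-disease association is
concave; with the bundled cohort sizes this effect is within the recovery
tolerances. The power formula uses the normal approximation, not the
noncentral t. No dominance, shared-household or bivariate-REML components
are modelled, and the scan is not engineered for genome-wide locus counts.
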