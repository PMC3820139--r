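# Small fixtures shared across test files; everything is generated in code.

two_locus_model <- function(p_a = 0.25, p_b = 0.24, r2 = 0.84, sign = 1) {
  loci <- locus_table(name = c("A", "B"), kind = c("snp", "snp"),
                      maf = c(p_a, p_b),
                      role = c("index_regulatory", "neutral"))
  build_haplotype_model(loci, data.frame(locus = "B", r2 = r2, sign = sign))
}

# brute-force maximum attainable r2 over a fine D grid subject to haplotype
# frequency feasibility (independent oracle for the closed-form bound)
grid_max_r2 <- function(p_a, p_b, n_grid = 200001) {
  q_a <- 1 - p_a; q_b <- 1 - p_b
  d <- seq(-0.25, 0.25, length.out = n_grid)
  ok <- (p_a * p_b + d) >= 0 & (p_a * q_b - d) >= 0 &
    (q_a * p_b - d) >= 0 & (q_a * q_b + d) >= 0
  max(d[ok]^2 / (p_a * q_a * p_b * q_b))
}

unrelated_cohort <- function(n, model = default_haplotype_model(), seed = 1) {
  ped <- simulate_pedigrees(n_unrelated = n)
  list(ped = ped,
       g = simulate_genotypes(model, ped, seed = seed),
       covar = simulate_covariates(n, seed + 1))
}

default_params_pair <- function(preset = "effect_match") {
  list(cfh = preset_biomarker_params("cfh", preset),
       cfhr1 = preset_biomarker_params("cfhr1", preset))
}

# a small fully-measured exposure+outcome cohort bundle for MR tests
small_iv_bundle <- function(n = 2000, seed = 11, theta = c(cfh = log(0.52),
                                                           cfhr1 = 0),
                            prevalence = 0.10) {
  m <- default_haplotype_model()
  params <- default_params_pair()
  tm <- biomarker_truth_moments(m, params)
  dp <- disease_params(gamma0 = stats::qlogis(prevalence), theta = theta,
                       delta = c(rs1061170 = log(1.69), rs800292 = log(0.47),
                                 rs388862 = log(0.96)))
  co <- unrelated_cohort(n, m, seed)
  bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = seed + 2)
  d <- simulate_disease(bio, co$g, co$covar, dp, tm$sd, tm$mean,
                        2 * stats::setNames(m$loci$maf, m$loci$name),
                        seed = seed + 3)
  list(cohorts = list(cc = list(role = "exposure_outcome", dosages = co$g,
                                covariates = co$covar, biomarkers = bio,
                                disease = d, kinship = NULL)),
       model = m, truth = list(theta = theta, dp = dp, tm = tm))
}
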