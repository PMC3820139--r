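#' Default multi-cohort study configuration
#'
#' Describes the four synthetic cohorts emulating the study layout: a
#' population biomarker cohort with relatedness (n = 1004), a case-control
#' series with biomarkers (382/201, of which 242 cases are flagged advanced),
#' a genotype-only case-control series (874/418) and an unrelated replication
#' population (n = 500). All cohorts share one haplotype model and one truth
#' record.
#'
#' @param biomarker_preset named character, preset per trait
#'   (`"effect_match"` or `"variance_match"`).
#' @param disease_preset `"causal"` (multivariate instrumental-variable
#'   truth) or `"observational"` (calibrated single-slope model).
#' @param onset `"none"` or `"cfhr1"` (apply the calibrated negative
#'   post-onset shift to measured CFHR1).
#' @param missing_rate MCAR genotype missingness rate.
#' @param rho_assay environmental correlation between the two assays.
#' @param prevalence population disease prevalence.
#' @param n_population,n_replication,n_cases_bio,n_controls_bio,
#'   n_advanced_bio,n_cases_geno,n_controls_geno cohort sizes.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(biomarker_preset = c(cfh = "effect_match",
                                               cfhr1 = "effect_match"),
                          disease_preset = "causal",
                          onset = "none",
                          missing_rate = 0.02,
                          rho_assay = 0,
                          prevalence = 0.10,
                          n_population = 1004,
                          n_replication = 500,
                          n_cases_bio = 382, n_controls_bio = 201,
                          n_advanced_bio = 242,
                          n_cases_geno = 874, n_controls_geno = 418) {
  stopifnot(disease_preset %in% c("causal", "observational"),
            onset %in% c("none", "cfhr1"))
  structure(list(
    biomarker_preset = biomarker_preset, disease_preset = disease_preset,
    onset = onset, missing_rate = missing_rate, rho_assay = rho_assay,
    prevalence = prevalence, n_population = n_population,
    n_replication = n_replication, n_cases_bio = n_cases_bio,
    n_controls_bio = n_controls_bio, n_advanced_bio = n_advanced_bio,
    n_cases_geno = n_cases_geno, n_controls_geno = n_controls_geno),
    class = "cohort_config")
}

# one simulated unrelated population with biomarkers and disease
simulate_population <- function(n, model, params, dparams, tm, config, seed) {
  ped <- simulate_pedigrees(n_unrelated = n)
  g <- simulate_genotypes(model, ped, seed = child_seed(seed, "geno"))
  covar <- simulate_covariates(n, seed = child_seed(seed, "covar"))
  bio <- simulate_biomarkers(g, covar, ped, params,
                             rho_assay = config$rho_assay,
                             seed = child_seed(seed, "bio"))
  maf <- setNames(model$loci$maf, model$loci$name)
  dis <- simulate_disease(bio, g, covar, dparams,
                          truth_sd = tm$sd, truth_mean = tm$mean,
                          dosage_mean = 2 * maf,
                          seed = child_seed(seed, "disease"))
  list(ped = ped, g = g, covar = covar, bio = bio, disease = dis)
}

mask_genotypes <- function(g, rate, seed) {
  if (rate <= 0) return(g)
  with_seed(seed, {
    g[stats::runif(length(g)) < rate] <- NA_integer_
    g
  })
}

#' Assemble the default four-cohort synthetic bundle
#'
#' Generates the four cohorts of [cohort_config()] from a single shared
#' haplotype model, records the full generating truth (all parameters,
#' analytic moments, calibrated constants and the seed) and returns a
#' `cohort_bundle`. Measured biomarkers include any configured post-onset
#' shift; latent values are kept in the truth record of the biomarker
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed; all stage seeds derive from it.
#' @return list of class `cohort_bundle` with elements `cohorts` (named list
#'   of cohort data), `model` (haplotype model) and `truth`.
#' @export
assemble_cohorts <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  model <- default_haplotype_model()
  params <- list(
    cfh = preset_biomarker_params("cfh", config$biomarker_preset[["cfh"]], model),
    cfhr1 = preset_biomarker_params("cfhr1", config$biomarker_preset[["cfhr1"]], model))
  tm <- biomarker_truth_moments(model, params, config$rho_assay)
  dparams <- preset_disease_params(config$disease_preset, tm, config$prevalence)
  onset_shift <- c(cfh = 0, cfhr1 = 0)
  if (config$onset == "cfhr1") {
    cf <- config$n_cases_bio / (config$n_cases_bio + config$n_controls_bio)
    onset_shift["cfhr1"] <- preset_onset_shift(model, params,
                                               config$rho_assay,
                                               case_fraction = cf)[["cfhr1"]]
  }

  cohorts <- list()

  ## population biomarker cohort with relatedness (no disease layer)
  n_fam <- floor(config$n_population / 6)
  n_unrel <- config$n_population - 4 * n_fam
  ped_pop <- simulate_pedigrees(n_families = n_fam, sibship_size = 2,
                                n_unrelated = n_unrel,
                                phenotype_parents = TRUE)
  s1 <- child_seed(seed, "population")
  g_pop <- simulate_genotypes(model, ped_pop, seed = child_seed(s1, "geno"))
  covar_pop <- simulate_covariates(nrow(ped_pop), child_seed(s1, "covar"))
  bio_pop <- simulate_biomarkers(g_pop, covar_pop, ped_pop, params,
                                 rho_assay = config$rho_assay,
                                 seed = child_seed(s1, "bio"))
  keep <- ped_pop$phenotyped
  cohorts$population <- list(
    role = "exposure_only",
    dosages = mask_genotypes(g_pop[keep, , drop = FALSE], config$missing_rate,
                             child_seed(s1, "mask")),
    covariates = covar_pop[keep, ],
    biomarkers = bio_pop[keep, ],
    disease = NULL,
    kinship = kinship_matrix(ped_pop, phenotyped_only = TRUE),
    pedigree = ped_pop)

  ## replication population, unrelated
  s2 <- child_seed(seed, "replication")
  ped_rep <- simulate_pedigrees(n_unrelated = config$n_replication)
  g_rep <- simulate_genotypes(model, ped_rep, seed = child_seed(s2, "geno"))
  covar_rep <- simulate_covariates(config$n_replication, child_seed(s2, "covar"))
  bio_rep <- simulate_biomarkers(g_rep, covar_rep, ped_rep, params,
                                 rho_assay = config$rho_assay,
                                 seed = child_seed(s2, "bio"))
  cohorts$replication <- list(
    role = "exposure_only",
    dosages = mask_genotypes(g_rep, config$missing_rate, child_seed(s2, "mask")),
    covariates = covar_rep, biomarkers = bio_rep,
    disease = NULL, kinship = NULL)

  ## case-control series with biomarkers
  s3 <- child_seed(seed, "casecontrol_bio")
  n_pool3 <- max(6000, ceiling((config$n_cases_bio / config$prevalence) * 1.6))
  pool3 <- simulate_population(n_pool3, model, params, dparams, tm, config, s3)
  sel3 <- sample_case_control(pool3$disease, config$n_cases_bio,
                              config$n_controls_bio, child_seed(s3, "sample"))
  measured3 <- apply_onset_shift(pool3$bio, pool3$disease, onset_shift)
  adv <- rep(FALSE, length(sel3))
  adv[seq_len(min(config$n_advanced_bio, config$n_cases_bio))] <- TRUE
  cohorts$casecontrol_bio <- list(
    role = "exposure_outcome",
    dosages = mask_genotypes(pool3$g[sel3, , drop = FALSE],
                             config$missing_rate, child_seed(s3, "mask")),
    covariates = pool3$covar[sel3, ],
    biomarkers = measured3[sel3, ],
    biomarkers_latent = pool3$bio[sel3, ],
    disease = pool3$disease[sel3],
    advanced = adv,
    kinship = NULL)

  ## genotype-only case-control series
  s4 <- child_seed(seed, "casecontrol_geno")
  n_pool4 <- max(12000, ceiling((config$n_cases_geno / config$prevalence) * 1.4))
  pool4 <- simulate_population(n_pool4, model, params, dparams, tm, config, s4)
  sel4 <- sample_case_control(pool4$disease, config$n_cases_geno,
                              config$n_controls_geno, child_seed(s4, "sample"))
  cohorts$casecontrol_geno <- list(
    role = "outcome_only",
    dosages = mask_genotypes(pool4$g[sel4, , drop = FALSE],
                             config$missing_rate, child_seed(s4, "mask")),
    covariates = pool4$covar[sel4, ],
    biomarkers = NULL,
    disease = pool4$disease[sel4],
    kinship = NULL)

  truth <- list(
    seed = seed, config = unclass(config),
    biomarker_params = lapply(params, unclass),
    disease_params = unclass(dparams),
    onset_shift = as.list(onset_shift),
    moments = list(mean = as.list(tm$mean), sd = as.list(tm$sd)),
    maf = as.list(setNames(model$loci$maf, model$loci$name)),
    ld_r2 = as.list(setNames(model$r2_target, model$loci$name)))
  structure(list(cohorts = cohorts, model = model, truth = truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle (seed", x$truth$seed, ")\n")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat(sprintf("  %-16s n = %4d  role = %-16s layers: %s\n", nm,
                nrow(co$dosages), co$role,
                paste(c("genotypes",
                        if (!is.null(co$biomarkers)) "biomarkers",
                        if (!is.null(co$disease)) "disease",
                        if (!is.null(co$kinship)) "kinship"), collapse = "+")))
  }
  invisible(x)
}
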