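#' Default locus panel for the regulators-of-complement-activation region
#'
#' Twelve variants: eleven SNPs and one common deletion, with the regulatory
#' index SNP tagged `index_regulatory` and the three non-synonymous coding
#' variants tagged `pleiotropic`. Minor-allele frequencies and pairwise LD to
#' the index SNP emulate a Western European population: the deletion is
#' tightly coupled to the index SNP (r2 = 0.84) while the coding variants are
#' only weakly coupled (r2 = 0.16 and 0.04).
#'
#' @return a [locus_table()].
#' @export
default_locus_table <- function() {
  locus_table(
    name = c("rs6677604", "CNP147", "rs1061170", "rs800292", "rs388862",
             "rs2274700", "rs1410996", "rs2019727", "rs1048663", "rs412852",
             "rs11582939", "rs1329428"),
    kind = c("snp", "deletion", rep("snp", 10)),
    maf  = c(0.25, 0.24, 0.35, 0.22, 0.15,
             0.30, 0.30, 0.28, 0.20, 0.30, 0.18, 0.45),
    role = c("index_regulatory", "neutral", "pleiotropic", "pleiotropic",
             "pleiotropic", rep("neutral", 7)))
}

#' Default pairwise LD targets to the index SNP
#'
#' r2 values for the deletion (0.84), the synonymous tag SNP (0.33) and the
#' two coding variants (0.16, 0.04) are the study conditions; the remaining
#' non-coding tag SNPs get moderate invented values.
#'
#' @return `data.frame` with columns `locus`, `r2`.
#' @export
default_ld_targets <- function() {
  data.frame(
    locus = c("CNP147", "rs1061170", "rs800292", "rs388862", "rs2274700",
              "rs1410996", "rs2019727", "rs1048663", "rs412852",
              "rs11582939", "rs1329428"),
    r2 = c(0.84, 0.16, 0.04, 0.02, 0.33, 0.50, 0.45, 0.35, 0.40, 0.30, 0.35))
}

#' Default haplotype model (12-locus panel with default LD targets)
#' @return a `haplotype_model`.
#' @export
default_haplotype_model <- function() {
  build_haplotype_model(default_locus_table(), default_ld_targets())
}

# variance of the default covariates (age ~ U(40,90), sex ~ Bern(0.5),
# bmi ~ N(27, 4)) and their reference means
covariate_moments <- function() {
  list(mean = c(age = 65, sex = 0.5, bmi = 27),
       var = c(age = 50^2 / 12, sex = 0.25, bmi = 16))
}

#' Biomarker generator presets
#'
#' Returns [biomarker_params()] for the CFH-like trait (plasma concentration
#' in ug/ml; population mean 400, SD 62, narrow-sense heritability 0.46) or
#' the CFHR1-like trait (plate-relative standardized units; mean 0.93,
#' heritability 0.69). Two presets resolve the internal tension between the
#' per-allele effect and the variance share of the index locus:
#'
#' * `"effect_match"`: the per-allele effect is fixed (25.6 ug/ml for the
#'   index SNP on CFH; the deletion effect on CFHR1 is set so the marginal
#'   index-SNP slope equals -0.23 per allele) and the single-locus variance
#'   share follows from `2 p q beta^2`.
#' * `"variance_match"`: the single-locus variance share is fixed (0.26 of
#'   covariate-adjusted variance for CFH, 0.40 for CFHR1) and the per-allele
#'   effect is derived.
#'
#' In both presets the total additive fraction (locus + polygenic) equals the
#' trait heritability, so the locus share of additive variance is 0.26/0.46
#' (about 57%) and 0.40/0.69 (about 58%) under `"variance_match"`. The CFHR1
#' total SD is set so the deletion-dosage/biomarker correlation is -0.62.
#'
#' @param trait `"cfh"` or `"cfhr1"`.
#' @param preset `"effect_match"` or `"variance_match"`.
#' @param model haplotype model supplying MAFs and LD (defaults to
#'   [default_haplotype_model()]).
#' @return a [biomarker_params()].
#' @export
preset_biomarker_params <- function(trait = c("cfh", "cfhr1"),
                                    preset = c("effect_match", "variance_match"),
                                    model = default_haplotype_model()) {
  trait <- match.arg(trait)
  preset <- match.arg(preset)
  cm <- covariate_moments()
  maf <- setNames(model$loci$maf, model$loci$name)
  if (trait == "cfh") {
    target_mean <- 400; v_tot <- 62^2; h2 <- 0.46; share <- 0.26
    locus <- "rs6677604"
    var_g <- 2 * maf[locus] * (1 - maf[locus])
    beta_l <- if (preset == "effect_match") 25.6 else sqrt(share * v_tot / var_g)
    covar_beta <- c(age = 0.15, sex = 4, bmi = 0.4)
  } else {
    h2 <- 0.69; share <- 0.40
    locus <- "CNP147"
    var_g <- 2 * maf[locus] * (1 - maf[locus])
    # deletion effect chosen so the marginal index-SNP slope is -0.23/allele:
    # slope_index = beta_del * D / (p_idx q_idx)
    d <- model$D[[locus]]
    p_idx <- model$p_index
    beta_eff <- -0.23 * p_idx * (1 - p_idx) / d
    # total SD set so cor(deletion dosage, trait) = -0.62
    v_tot <- (abs(beta_eff) * sqrt(var_g) / 0.62)^2
    target_mean <- 0.93
    beta_l <- if (preset == "effect_match") beta_eff else
      -sqrt(share * v_tot / var_g)
    covar_beta <- c(age = 2e-4, sex = 5e-3, bmi = 5e-4)
  }
  var_snp <- var_g * beta_l^2
  sigma2_poly <- h2 * v_tot - var_snp
  if (sigma2_poly < 0) stop("locus variance exceeds heritability budget")
  sigma2_env <- (1 - h2) * v_tot
  beta <- setNames(beta_l, locus)
  intercept <- target_mean - sum(beta * 2 * maf[names(beta)]) -
    sum(covar_beta * cm$mean[names(covar_beta)])
  biomarker_params(intercept = intercept, beta = beta,
                   covar_beta = covar_beta, sigma2_poly = sigma2_poly,
                   sigma2_env = sigma2_env)
}

#' Analytic moments of a simulated biomarker pair
#'
#' Means, total SDs and the 2 x 2 covariance of the two traits implied by the
#' generator parameters (genetic part from [dosage_covariance()], polygenic
#' and environmental variances, covariate contributions).
#'
#' @param model haplotype model.
#' @param params named list of two [biomarker_params()].
#' @param rho_assay environmental correlation between the two traits.
#' @return list with `mean` (2-vector), `sd` (2-vector), `cov` (2 x 2),
#'   `cov_with_covariates` (2 x 3 matrix over age/sex/bmi).
#' @export
biomarker_truth_moments <- function(model, params, rho_assay = 0) {
  cm <- covariate_moments()
  gcov <- dosage_covariance(model)
  nm <- rownames(gcov)
  B <- matrix(0, 2, length(nm), dimnames = list(names(params), nm))
  Cb <- matrix(0, 2, 3, dimnames = list(names(params), c("age", "sex", "bmi")))
  mu <- numeric(2)
  for (j in 1:2) {
    p <- params[[j]]
    B[j, names(p$beta)] <- p$beta
    Cb[j, names(p$covar_beta)] <- p$covar_beta
    mu[j] <- p$intercept +
      sum(p$beta * 2 * setNames(model$loci$maf, model$loci$name)[names(p$beta)]) +
      sum(p$covar_beta * cm$mean[names(p$covar_beta)])
  }
  S <- B %*% gcov %*% t(B)
  S <- S + diag(c(params[[1]]$sigma2_poly, params[[2]]$sigma2_poly))
  env_sd <- sqrt(c(params[[1]]$sigma2_env, params[[2]]$sigma2_env))
  env <- diag(env_sd^2)
  env[1, 2] <- env[2, 1] <- rho_assay * env_sd[1] * env_sd[2]
  S <- S + env
  S <- S + Cb %*% diag(cm$var) %*% t(Cb)
  cov_w <- sweep(Cb, 2, cm$var[colnames(Cb)], "*")
  list(mean = setNames(mu, names(params)),
       sd = setNames(sqrt(diag(S)), names(params)),
       cov = S, cov_with_covariates = cov_w)
}

#' Solve for the disease-model slope that yields a target case-control gap
#'
#' For a standardized biomarker `x ~ N(0, 1)` and
#' `P(D = 1 | x) = plogis(gamma0 + theta x)`, the expected case-minus-control
#' difference in `x` is computed by numerical integration and the slope
#' `theta` solved so the gap equals `gap_sd` (in SD units; negative means
#' cases lower).
#'
#' @param gap_sd target case-minus-control mean difference in SD units.
#' @param prevalence population disease prevalence fixing `gamma0`.
#' @return the log-odds slope `theta` per SD.
#' @export
calibrate_gap_slope <- function(gap_sd, prevalence = 0.10) {
  gamma0 <- stats::qlogis(prevalence)
  gap <- function(theta) {
    f1 <- function(x) x * stats::plogis(gamma0 + theta * x) * stats::dnorm(x)
    f0 <- function(x) x * (1 - stats::plogis(gamma0 + theta * x)) * stats::dnorm(x)
    p1 <- function(x) stats::plogis(gamma0 + theta * x) * stats::dnorm(x)
    e1 <- stats::integrate(f1, -8, 8)$value
    ep <- stats::integrate(p1, -8, 8)$value
    e1 / ep - (-e1) / (1 - ep)   # E[x] = 0, so E[x (1-p)] = -E[x p]
  }
  if (gap_sd == 0) return(0)
  stats::uniroot(function(th) gap(th) - gap_sd,
                 lower = -5, upper = 5, tol = 1e-10)$root
}

#' Solve for the post-onset shift that yields a target conditional odds ratio
#'
#' With disease affecting the measured (but not latent) value of a biomarker,
#' the induced logistic slope on the measured value, conditional on a
#' covariate set W, is `delta / sigma_c^2` per unit, where `sigma_c^2` is the
#' residual variance of the latent biomarker given W. This inverts that
#' relation to find the shift `delta` giving a target odds ratio per 1 sample
#' SD, accounting for the SD inflation the shift itself causes in a
#' case-control sample.
#'
#' @param target_or target conditional odds ratio per 1 SD of the measured
#'   biomarker.
#' @param sigma_c2 residual variance of the latent biomarker given the
#'   adjustment covariates.
#' @param sd_marginal marginal latent SD of the biomarker.
#' @param case_fraction case fraction of the analysis sample.
#' @return the onset shift in trait units.
#' @export
calibrate_onset_shift <- function(target_or, sigma_c2, sd_marginal,
                                  case_fraction = 382 / 583) {
  l <- log(target_or)
  delta <- l * sigma_c2 / sd_marginal
  for (i in 1:5) {
    sd_samp <- sqrt(sd_marginal^2 + case_fraction * (1 - case_fraction) * delta^2)
    delta <- l * sigma_c2 / sd_samp
  }
  delta
}

#' Disease-model presets
#'
#' * `"causal"`: the multivariate truth used by the instrumental-variable
#'   bundle: causal log-OR per SD of CFH `log(0.52)`, null causal CFHR1
#'   effect, and direct per-allele log-ORs for the three coding variants
#'   (`log(1.69)` risk for the exon-9 variant, `log(0.47)` protective for the
#'   exon-2 variant, `log(0.96)` null for the CFHR1 coding variant).
#' * `"observational"`: a single-slope model calibrated with
#'   [calibrate_gap_slope()] so the expected case-control CFH gap equals
#'   15.7 ug/ml, used by the observational case-control stage; no direct
#'   genetic effects.
#'
#' @param preset `"causal"` or `"observational"`.
#' @param truth output of [biomarker_truth_moments()] for the bundle's
#'   biomarker parameters (needed to express the gap in SD units).
#' @param prevalence population prevalence.
#' @return a [disease_params()].
#' @export
preset_disease_params <- function(preset = c("causal", "observational"),
                                  truth, prevalence = 0.10) {
  preset <- match.arg(preset)
  gamma0 <- stats::qlogis(prevalence)
  if (preset == "causal") {
    disease_params(
      gamma0 = gamma0,
      theta = c(cfh = log(0.52), cfhr1 = 0),
      delta = c(rs1061170 = log(1.69), rs800292 = log(0.47),
                rs388862 = log(0.96)))
  } else {
    gap_sd <- -15.7 / truth$sd[["cfh"]]
    disease_params(
      gamma0 = gamma0,
      theta = c(cfh = calibrate_gap_slope(gap_sd, prevalence), cfhr1 = 0))
  }
}

#' Onset-shift preset reproducing the conditional CFHR1-disease association
#'
#' Returns the CFHR1 onset shift (trait units, negative) such that logistic
#' regression of disease on measured CFHR1 adjusted for CFH, age and sex
#' yields an odds ratio of 0.72 per 1 SD, even though the latent (pre-onset)
#' CFHR1 has no effect on disease in the generator.
#'
#' @param model haplotype model.
#' @param params biomarker parameter list (cfh, cfhr1).
#' @param rho_assay environmental correlation.
#' @param case_fraction case fraction of the target case-control series.
#' @return named vector `c(cfhr1 = shift)`.
#' @export
preset_onset_shift <- function(model, params, rho_assay = 0,
                               case_fraction = 382 / 583) {
  tm <- biomarker_truth_moments(model, params, rho_assay)
  cm <- covariate_moments()
  # residual variance of latent cfhr1 given (cfh, age, sex)
  v_w <- diag(c(tm$cov[1, 1], cm$var["age"], cm$var["sex"]))
  v_w[1, 2] <- v_w[2, 1] <- tm$cov_with_covariates["cfh", "age"]
  v_w[1, 3] <- v_w[3, 1] <- tm$cov_with_covariates["cfh", "sex"]
  c_vec <- c(tm$cov[2, 1], tm$cov_with_covariates["cfhr1", "age"],
             tm$cov_with_covariates["cfhr1", "sex"])
  sigma_c2 <- tm$cov[2, 2] - drop(t(c_vec) %*% solve(v_w, c_vec))
  c(cfhr1 = calibrate_onset_shift(0.72, sigma_c2, tm$sd[["cfhr1"]],
                                  case_fraction))
}
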