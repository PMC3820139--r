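#' Gene-drop genotypes through a pedigree from a haplotype model
#'
#' Founders receive two independent haplotypes drawn from the model
#' (Hardy-Weinberg equilibrium); each offspring inherits one randomly chosen
#' haplotype from each parent. Haplotypes span the whole locus block without
#' recombination, which is appropriate for a single sub-megabase region.
#'
#' @param model a [build_haplotype_model()] object.
#' @param pedigree a `pedigree`; unrelated cohorts are pedigrees of founders.
#' @param seed integer seed.
#' @param missing_rate per-entry probability that a dosage is masked as
#'   missing (missing completely at random); default 0.
#' @return integer matrix (individuals x loci) of minor/deletion allele
#'   dosages 0/1/2 with `NA` for missing entries; rownames are pedigree ids.
#' @export
simulate_genotypes <- function(model, pedigree, seed,
                               missing_rate = 0) {
  stopifnot(inherits(model, "haplotype_model"), missing_rate >= 0,
            missing_rate < 1)
  n <- nrow(pedigree)
  L <- nrow(model$loci)
  with_seed(seed, {
    hap1 <- matrix(0L, n, L)
    hap2 <- matrix(0L, n, L)
    fa <- match(pedigree$father, pedigree$id)
    mo <- match(pedigree$mother, pedigree$id)
    founder <- is.na(fa)
    nf <- sum(founder)
    if (nf > 0) {
      hap1[founder, ] <- draw_haplotypes(model, nf)
      hap2[founder, ] <- draw_haplotypes(model, nf)
    }
    for (k in which(!founder)) {
      hap1[k, ] <- if (stats::runif(1) < 0.5) hap1[fa[k], ] else hap2[fa[k], ]
      hap2[k, ] <- if (stats::runif(1) < 0.5) hap1[mo[k], ] else hap2[mo[k], ]
    }
    g <- hap1 + hap2
    dimnames(g) <- list(pedigree$id, model$loci$name)
    if (missing_rate > 0) {
      g[stats::runif(length(g)) < missing_rate] <- NA_integer_
    }
    g
  })
}

# n haplotypes from the chain factorization: index allele first, then each
# locus conditionally independent given the index allele
draw_haplotypes <- function(model, n) {
  L <- nrow(model$loci)
  idx <- which(model$loci$name == model$index)
  h <- matrix(0L, n, L)
  a <- stats::runif(n) < model$p_index
  h[, idx] <- as.integer(a)
  p <- ifelse(a, 1, 0) %o% model$cond1 + ifelse(a, 0, 1) %o% model$cond0
  u <- matrix(stats::runif(n * L), n, L)
  h2 <- (u < p) * 1L
  h2[, idx] <- as.integer(a)
  h2
}

#' Default biomarker covariate table
#'
#' Age uniform on 40-90 years, sex coded 0/1 with probability one half, BMI
#' normal with mean 27 and SD 4 kg/m^2. These distributions are stated
#' defaults of the generator, not estimates.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return `data.frame` with columns `age`, `sex`, `bmi`.
#' @export
simulate_covariates <- function(n, seed) {
  with_seed(seed, data.frame(
    age = stats::runif(n, 40, 90),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, 27, 4)))
}

#' Parameter set for one simulated plasma biomarker
#'
#' @param intercept trait intercept in concentration units.
#' @param beta named per-allele effects (trait units per minor/deletion
#'   allele); names must be locus names. Loci not named have effect 0.
#' @param covar_beta named effects for `age`, `sex`, `bmi` (any subset).
#' @param sigma2_poly polygenic variance (kinship-structured additive
#'   background).
#' @param sigma2_env independent environmental/assay variance.
#' @param onset_shift additive change applied to the measured value of
#'   affected individuals ([apply_onset_shift()]); 0 disables.
#' @return list of class `biomarker_params`.
#' @export
biomarker_params <- function(intercept, beta = c(), covar_beta = c(),
                             sigma2_poly = 0, sigma2_env = 1,
                             onset_shift = 0) {
  if (sigma2_poly < 0 || sigma2_env < 0) stop("variances must be nonnegative")
  structure(list(intercept = intercept, beta = beta, covar_beta = covar_beta,
                 sigma2_poly = sigma2_poly, sigma2_env = sigma2_env,
                 onset_shift = onset_shift),
            class = "biomarker_params")
}

# polygenic values with covariance sigma2 * K sampled by gene dropping:
# founders ~ N(0, sigma2); offspring = midparent + N(0, sigma2 / 2)
sample_polygenic <- function(pedigree, sigma2) {
  n <- nrow(pedigree)
  a <- numeric(n)
  if (sigma2 == 0) return(a)
  fa <- match(pedigree$father, pedigree$id)
  mo <- match(pedigree$mother, pedigree$id)
  founder <- is.na(fa)
  a[founder] <- stats::rnorm(sum(founder), 0, sqrt(sigma2))
  for (k in which(!founder)) {
    a[k] <- 0.5 * (a[fa[k]] + a[mo[k]]) + stats::rnorm(1, 0, sqrt(sigma2 / 2))
  }
  a
}

#' Simulate two plasma biomarkers with genetic, polygenic and covariate parts
#'
#' Each trait is `intercept + dosages %*% beta + covariate terms + polygenic +
#' environmental noise`. The two traits' environmental components may be
#' correlated (`rho_assay`, emulating assay cross-reactivity); their polygenic
#' components are independent, so any genetic correlation arises through
#' shared or linked causal loci.
#'
#' @param dosages dosage matrix from [simulate_genotypes()]. Missing entries
#'   are treated as their locus mean when forming genetic values (the
#'   generating haplotypes are complete; masking is applied afterwards), so
#'   pass the unmasked matrix here.
#' @param covariates `data.frame` from [simulate_covariates()].
#' @param pedigree the `pedigree` used for the dosages.
#' @param params named list of two [biomarker_params()], e.g.
#'   `list(cfh = ..., cfhr1 = ...)`.
#' @param rho_assay correlation of the environmental components, `|rho| < 1`.
#' @param seed integer seed.
#' @return `data.frame` of latent (pre-onset) biomarker values, one column
#'   per trait, with the polygenic draws stored in `attr(, "polygenic")`.
#' @export
simulate_biomarkers <- function(dosages, covariates, pedigree, params,
                                rho_assay = 0, seed) {
  stopifnot(length(params) == 2L, abs(rho_assay) < 1,
            nrow(dosages) == nrow(pedigree),
            nrow(covariates) == nrow(pedigree))
  n <- nrow(dosages)
  with_seed(seed, {
    # correlated environmental pair
    e1 <- stats::rnorm(n)
    e2 <- rho_assay * e1 + sqrt(1 - rho_assay^2) * stats::rnorm(n)
    env <- cbind(e1, e2)
    out <- matrix(NA_real_, n, 2L)
    poly <- matrix(0, n, 2L)
    for (j in 1:2) {
      p <- params[[j]]
      stopifnot(inherits(p, "biomarker_params"))
      y <- rep(p$intercept, n)
      for (nm in names(p$beta)) {
        g <- dosages[, nm]
        if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
        y <- y + p$beta[[nm]] * g
      }
      for (nm in names(p$covar_beta)) {
        y <- y + p$covar_beta[[nm]] * covariates[[nm]]
      }
      poly[, j] <- sample_polygenic(pedigree, p$sigma2_poly)
      out[, j] <- y + poly[, j] + sqrt(p$sigma2_env) * env[, j]
    }
    colnames(out) <- names(params)
    res <- as.data.frame(out)
    attr(res, "polygenic") <- poly
    res
  })
}

#' Parameter set for the logistic disease model
#'
#' @param gamma0 baseline log-odds (log odds of disease at standardized
#'   biomarkers 0, centered pleiotropy dosages and centered covariates).
#' @param theta named causal log-odds ratios per 1 SD of each biomarker
#'   (names must match the biomarker columns).
#' @param delta named direct per-allele log-odds ratios for pleiotropic loci.
#' @param covar_gamma named covariate log-odds ratios (`age`, `sex`, `bmi`).
#' @return list of class `disease_params`.
#' @export
disease_params <- function(gamma0, theta, delta = c(), covar_gamma = c()) {
  stopifnot(is.finite(gamma0), all(is.finite(theta)))
  structure(list(gamma0 = gamma0, theta = theta, delta = delta,
                 covar_gamma = covar_gamma), class = "disease_params")
}

#' Simulate disease status from latent biomarkers and genotypes
#'
#' `P(D = 1) = plogis(gamma0 + theta' x_std + delta' (g - 2 maf) + covariate
#' terms)` where `x_std` are the latent biomarkers standardized by the
#' generator's analytic total SD (`truth_sd`), and pleiotropy dosages are
#' centered at their expectation so that `gamma0 = qlogis(prevalence)` holds
#' at the reference covariate values.
#'
#' @param biomarkers latent biomarker `data.frame` (pre-onset values).
#' @param dosages dosage matrix (unmasked).
#' @param covariates covariate `data.frame`.
#' @param params a [disease_params()].
#' @param truth_sd named generator total SDs used to standardize each
#'   biomarker.
#' @param truth_mean named generator means used to center each biomarker.
#' @param dosage_mean named expected dosages (2 * maf) for pleiotropy loci.
#' @param seed integer seed.
#' @return integer 0/1 disease vector.
#' @export
simulate_disease <- function(biomarkers, dosages, covariates, params,
                             truth_sd, truth_mean, dosage_mean = NULL, seed) {
  stopifnot(inherits(params, "disease_params"))
  n <- nrow(biomarkers)
  eta <- rep(params$gamma0, n)
  for (nm in names(params$theta)) {
    x_std <- (biomarkers[[nm]] - truth_mean[[nm]]) / truth_sd[[nm]]
    eta <- eta + params$theta[[nm]] * x_std
  }
  for (nm in names(params$delta)) {
    g <- dosages[, nm]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    ctr <- if (!is.null(dosage_mean) && nm %in% names(dosage_mean)) {
      dosage_mean[[nm]]
    } else mean(g)
    eta <- eta + params$delta[[nm]] * (g - ctr)
  }
  for (nm in names(params$covar_gamma)) {
    eta <- eta + params$covar_gamma[[nm]] *
      (covariates[[nm]] - mean(covariates[[nm]]))
  }
  with_seed(seed, as.integer(stats::runif(n) < stats::plogis(eta)))
}

#' Apply a post-onset shift to measured biomarker values
#'
#' Disease may alter a biomarker after onset, so the measured value in
#' affected individuals is the latent (pre-onset) value plus `onset_shift`.
#' The latent values are preserved by the caller's truth record; this
#' function only produces the measured table.
#'
#' @param biomarkers latent biomarker `data.frame`.
#' @param disease 0/1 vector.
#' @param onset_shift named vector of shifts (trait units) per biomarker;
#'   traits not named are unshifted.
#' @return measured biomarker `data.frame`.
#' @export
apply_onset_shift <- function(biomarkers, disease, onset_shift) {
  stopifnot(length(disease) == nrow(biomarkers))
  out <- biomarkers
  for (nm in names(onset_shift)) {
    if (!nm %in% names(out)) stop("unknown biomarker in onset_shift: ", nm)
    out[[nm]] <- out[[nm]] + onset_shift[[nm]] * disease
  }
  out
}

#' Sample a case-control series from a simulated population
#'
#' @param disease 0/1 vector over the population.
#' @param n_cases,n_controls requested counts.
#' @param seed integer seed.
#' @return integer vector of selected row indices (cases first), sampled
#'   without replacement.
#' @export
sample_case_control <- function(disease, n_cases, n_controls, seed) {
  cases <- which(disease == 1L)
  controls <- which(disease == 0L)
  if (length(cases) < n_cases) {
    stop(sprintf("population has %d cases, %d requested", length(cases), n_cases))
  }
  if (length(controls) < n_controls) {
    stop(sprintf("population has %d controls, %d requested",
                 length(controls), n_controls))
  }
  with_seed(seed, {
    c(sample(cases, n_cases), sample(controls, n_controls))
  })
}
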