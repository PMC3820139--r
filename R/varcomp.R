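#' Narrow-sense heritability by kinship-based REML
#'
#' Point estimate and standard error of `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)` from the null polygenic mixed model of
#' [fit_polygenic_null()]. Heritability is the proportion of the
#' covariate-adjusted phenotypic variance attributable to additive genetic
#' variance; the SE comes from the curvature of the restricted
#' log-likelihood at the optimum and is flagged unreliable at the 0/1
#' boundary.
#'
#' @inheritParams fit_polygenic_null
#' @return `data.frame` of class `varcomp_result` with columns `h2`, `se_h2`,
#'   `sigma2_g`, `sigma2_e`, `boundary`.
#' @export
estimate_h2 <- function(trait, covariates = NULL, kinship, eigen_k = NULL) {
  fit <- fit_polygenic_null(trait, covariates, kinship, eigen_k)
  out <- data.frame(h2 = fit$h2, se_h2 = fit$se_h2,
                    sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                    boundary = fit$boundary)
  class(out) <- c("varcomp_result", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Single-locus variance partition in the polygenic mixed model
#'
#' Fits the polygenic model with one locus as an additional fixed effect and
#' decomposes the covariate-adjusted phenotypic variance into the locus
#' share (`beta^2 Var(g)`), the residual polygenic share and the
#' environmental share; the three shares sum to one.
#' `snp_share_additive` is the locus share of total additive genetic
#' variance, `snp_share_total / (snp_share_total + polygenic share)`.
#'
#' @param trait numeric trait vector.
#' @param covariates optional covariate `data.frame`.
#' @param kinship additive relationship matrix.
#' @param dosage dosage vector for the partitioned locus.
#' @param eigen_k optional precomputed eigendecomposition of `kinship`.
#' @return `data.frame` of class `varcomp_result` with columns `h2`,
#'   `se_h2`, `snp_share_total`, `snp_share_additive`, `polygenic_share`,
#'   `env_share`, `beta`, `boundary`. `h2` here is the total additive
#'   fraction (locus + polygenic).
#' @export
snp_variance_partition <- function(trait, covariates = NULL, kinship, dosage,
                                   eigen_k = NULL) {
  g <- dosage
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) stop("zero-variance (monomorphic) dosage")
  cov2 <- if (is.null(covariates)) data.frame(snp_dosage = g) else
    cbind(covariates, snp_dosage = g)
  fit <- fit_polygenic_null(trait, cov2, kinship, eigen_k)
  beta <- fit$fixef[length(fit$fixef)]
  v_snp <- beta^2 * stats::var(g)
  v_tot <- v_snp + fit$sigma2_g + fit$sigma2_e
  snp_total <- v_snp / v_tot
  poly_share <- fit$sigma2_g / v_tot
  env_share <- fit$sigma2_e / v_tot
  out <- data.frame(
    h2 = snp_total + poly_share, se_h2 = fit$se_h2,
    snp_share_total = snp_total,
    snp_share_additive = snp_total / (snp_total + poly_share),
    polygenic_share = poly_share, env_share = env_share,
    beta = unname(beta), boundary = fit$boundary)
  class(out) <- c("varcomp_result", "data.frame")
  out
}
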