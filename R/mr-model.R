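#' Specification of the Bayesian instrumental-variable model
#'
#' Declares which loci act as instruments (non-coding variants assumed to
#' affect disease only through the biomarkers) and which as pleiotropy
#' covariates (coding variants granted a direct path to disease so the
#' instruments stay valid), which covariates enter both sub-models, and the
#' prior scales.
#'
#' @param instruments character vector of instrument locus names.
#' @param pleiotropy character vector of pleiotropy locus names (disjoint
#'   from the instruments).
#' @param exposures names of the two biomarker columns.
#' @param covariates covariate names entering both sub-models (standardized
#'   internally).
#' @param prior_sd_coef prior SD of standardized regression coefficients and
#'   log-odds ratios (normal, mean 0).
#' @param prior_sd_sigma half-normal prior SD for the exposure residual SDs
#'   (on the standardized exposure scale).
#' @param use_case_biomarkers if `TRUE` (default), measured biomarkers of
#'   affected individuals enter the disease (outcome) model, which remains
#'   valid under case-control sampling; if `FALSE` they are discarded and
#'   treated as latent. In either setting the Gaussian exposure model is
#'   fitted only to population cohorts and unaffected controls, because
#'   case enrichment tilts the biomarker distribution of affected
#'   individuals and would otherwise distort the genotype-biomarker
#'   equations.
#' @return list of class `iv_model_spec`.
#' @export
iv_model_spec <- function(instruments = c("rs6677604", "CNP147"),
                          pleiotropy = c("rs1061170", "rs800292", "rs388862"),
                          exposures = c("cfh", "cfhr1"),
                          covariates = c("age", "sex"),
                          prior_sd_coef = 2,
                          prior_sd_sigma = 3,
                          use_case_biomarkers = TRUE) {
  if (length(intersect(instruments, pleiotropy))) {
    stop("instrument and pleiotropy sets must be disjoint")
  }
  stopifnot(length(exposures) == 2L)
  structure(list(instruments = instruments, pleiotropy = pleiotropy,
                 exposures = exposures, covariates = covariates,
                 prior_sd_coef = prior_sd_coef,
                 prior_sd_sigma = prior_sd_sigma,
                 use_case_biomarkers = use_case_biomarkers),
            class = "iv_model_spec")
}

#' Build the joint multi-cohort instrumental-variable model
#'
#' Assembles the data structures for the joint Bayesian model
#' \deqn{(X_1, X_2) = \alpha_c + B G + C Z + \epsilon,\quad
#'       \epsilon \sim N_2(0, \Sigma)}
#' \deqn{\mathrm{logit}\, P(D = 1) = \gamma_c + \theta^\top X_{std} +
#'       \delta^\top G_{pleio} + \phi^\top Z}
#' over all cohorts of a bundle: exposures are observed where measured and
#' latent otherwise; each case-control cohort gets a free intercept
#' `gamma_c` (absorbing ascertainment); missing genotypes are model
#' parameters with categorical priors (instrument-pair entries use the
#' EM-fitted two-locus haplotype frequencies, so phase uncertainty between
#' the coupled instruments propagates; other loci use marginal
#' Hardy-Weinberg priors). Exposures are standardized by the pooled mean/SD
#' of the exposure-measured cohorts, so `theta` is a log-odds ratio per 1 SD.
#'
#' @param bundle a `cohort_bundle` (or a compatible named list of cohorts).
#' @param spec an [iv_model_spec()].
#' @param cohorts names of cohorts to include; default all with a usable
#'   layer.
#' @param advanced_only in exposure+outcome cohorts carrying an `advanced`
#'   flag, keep only advanced cases plus all controls.
#' @param outcome_family `"binomial"` (logistic disease model) or
#'   `"gaussian"` (identity-link variant, used for validation against
#'   two-stage least squares).
#' @return object of class `iv_model`.
#' @export
build_iv_model <- function(bundle, spec = iv_model_spec(),
                           cohorts = names(bundle$cohorts),
                           advanced_only = TRUE,
                           outcome_family = c("binomial", "gaussian")) {
  outcome_family <- match.arg(outcome_family)
  stopifnot(inherits(spec, "iv_model_spec"))
  loci <- c(spec$instruments, spec$pleiotropy)
  co_list <- bundle$cohorts[cohorts]

  rows <- list()
  for (nm in names(co_list)) {
    co <- co_list[[nm]]
    has_x <- !is.null(co$biomarkers)
    has_d <- !is.null(co$disease)
    if (!has_x && !has_d) stop("cohort '", nm, "' has neither exposures nor outcome")
    if (!all(loci %in% colnames(co$dosages))) {
      stop("cohort '", nm, "' lacks a required locus")
    }
    keep <- rep(TRUE, nrow(co$dosages))
    if (has_x && has_d && advanced_only && !is.null(co$advanced)) {
      keep <- co$advanced | co$disease == 0L
    }
    X <- if (has_x) as.matrix(co$biomarkers[keep, spec$exposures]) else NULL
    x_meas <- has_x & rep(TRUE, sum(keep))
    if (has_x && has_d && !spec$use_case_biomarkers) {
      x_meas <- co$disease[keep] == 0L
    }
    # exposure-model (Gaussian) rows: measured values of individuals not
    # ascertained on the outcome, i.e. population cohorts and controls;
    # only relevant for case-control (binomial) outcomes
    x_expo <- x_meas
    if (has_x && has_d && outcome_family == "binomial") {
      x_expo <- x_meas & co$disease[keep] == 0L
    }
    rows[[nm]] <- list(
      name = nm,
      G = co$dosages[keep, loci, drop = FALSE],
      Z = as.matrix(co$covariates[keep, spec$covariates, drop = FALSE]),
      X = X, x_meas = if (has_x) x_meas else rep(FALSE, sum(keep)),
      x_expo = if (has_x) x_expo else rep(FALSE, sum(keep)),
      D = if (has_d) co$disease[keep] else NULL)
  }

  # standardization constants: pooled over exposure-model rows
  xm <- do.call(rbind, lapply(rows, function(r) {
    if (!is.null(r$X)) r$X[r$x_expo, , drop = FALSE] else NULL
  }))
  if (is.null(xm) || nrow(xm) < 10) stop("no exposure-measured cohort available")
  x_center <- colMeans(xm)
  x_scale <- apply(xm, 2, stats::sd)

  z_all <- do.call(rbind, lapply(rows, function(r) r$Z))
  z_center <- colMeans(z_all)
  z_scale <- apply(z_all, 2, stats::sd)

  # genotype priors for missing entries
  g_all <- do.call(rbind, lapply(rows, function(r) r$G))
  maf_hat <- colMeans(g_all, na.rm = TRUE) / 2
  hwe_prior <- rbind((1 - maf_hat)^2, 2 * maf_hat * (1 - maf_hat), maf_hat^2)
  pair_cond <- NULL
  if (length(spec$instruments) >= 2) {
    a <- g_all[, spec$instruments[1]]; b <- g_all[, spec$instruments[2]]
    em <- em_haplotype_freqs(a, b)
    f <- em$freqs   # ab aB Ab AB, first position = instrument 1
    hap_a <- c(ab = 0, aB = 0, Ab = 1, AB = 1)
    hap_b <- c(ab = 0, aB = 1, Ab = 0, AB = 1)
    # joint genotype probabilities P(g_a = i, g_b = j) under HWE
    joint <- matrix(0, 3, 3)
    for (u in names(f)) for (v in names(f)) {
      i <- hap_a[[u]] + hap_a[[v]]; j <- hap_b[[u]] + hap_b[[v]]
      joint[i + 1, j + 1] <- joint[i + 1, j + 1] + f[[u]] * f[[v]]
    }
    pair_cond <- joint
  }

  structure(list(
    spec = spec, rows = rows, loci = loci,
    outcome_family = outcome_family,
    x_center = x_center, x_scale = x_scale,
    z_center = z_center, z_scale = z_scale,
    maf_hat = maf_hat, hwe_prior = hwe_prior, pair_joint = pair_cond),
    class = "iv_model")
}

#' Number of sampled (non-latent, non-missing) parameters of an iv_model
#' @param model an `iv_model`.
#' @return integer count: exposure coefficients, residual covariance,
#'   outcome coefficients (and the gaussian outcome SD if applicable).
#' @export
n_parameters <- function(model) {
  n_mcoh <- sum(vapply(model$rows, function(r) any(r$x_expo), TRUE))
  n_ocoh <- sum(vapply(model$rows, function(r) !is.null(r$D), TRUE))
  L <- length(model$loci)
  nz <- length(model$spec$covariates)
  p_w <- n_mcoh + L + nz
  2L * p_w + 3L + (n_ocoh + 2L + length(model$spec$pleiotropy) + nz) +
    as.integer(model$outcome_family == "gaussian")
}

#' @export
print.iv_model <- function(x, ...) {
  n <- sum(vapply(x$rows, function(r) nrow(r$G), 0))
  n_lat <- sum(vapply(x$rows, function(r) sum(!r$x_meas), 0))
  cat("Bayesian instrumental-variable model:\n")
  cat("  cohorts:", paste(names(x$rows), collapse = ", "), "\n")
  cat(sprintf("  %d individuals (%d with latent exposures), %d loci (%d instruments, %d pleiotropy), %d sampled parameters\n",
              n, n_lat, length(x$loci), length(x$spec$instruments),
              length(x$spec$pleiotropy), n_parameters(x)))
  invisible(x)
}
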