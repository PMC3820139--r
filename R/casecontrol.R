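#' Case-control biomarker comparison
#'
#' Unadjusted two-sided two-sample t-test (pooled variance by default, Welch
#' by flag) plus a covariate-adjusted comparison from the disease-indicator
#' coefficient in a linear model of the biomarker on disease and covariates.
#' The difference is also expressed in pooled-SD units.
#'
#' @param biomarker numeric vector.
#' @param disease 0/1 vector.
#' @param covariates optional covariate `data.frame` for the adjusted test.
#' @param welch use the Welch (unequal-variance) t-test instead of pooled.
#' @return `data.frame` of class `group_comparison` with columns
#'   `mean_cases`, `mean_controls`, `sem_cases`, `sem_controls`,
#'   `difference` (cases minus controls), `difference_sd_units`,
#'   `p_unadjusted`, `p_adjusted`, `adjusted_difference`.
#' @export
compare_means <- function(biomarker, disease, covariates = NULL,
                          welch = FALSE) {
  keep <- is.finite(biomarker) & !is.na(disease)
  y <- biomarker[keep]; d <- disease[keep]
  y1 <- y[d == 1]; y0 <- y[d == 0]
  if (length(y1) < 2 || length(y0) < 2) stop("each group needs at least 2 observations")
  tt <- stats::t.test(y1, y0, var.equal = !welch)
  n1 <- length(y1); n0 <- length(y0)
  sd_pooled <- sqrt(((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
                      (n1 + n0 - 2))
  p_adj <- NA_real_; diff_adj <- NA_real_
  if (!is.null(covariates)) {
    df <- cbind(data.frame(y = y, d = d), covariates[keep, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    p_adj <- cf["d", "Pr(>|t|)"]
    diff_adj <- cf["d", "Estimate"]
  }
  out <- data.frame(
    mean_cases = mean(y1), mean_controls = mean(y0),
    sem_cases = stats::sd(y1) / sqrt(n1),
    sem_controls = stats::sd(y0) / sqrt(n0),
    difference = mean(y1) - mean(y0),
    difference_sd_units = (mean(y1) - mean(y0)) / sd_pooled,
    p_unadjusted = tt$p.value, p_adjusted = p_adj,
    adjusted_difference = diff_adj)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Odds ratio per 1 SD of a biomarker from logistic regression
#'
#' Maximum-likelihood logistic regression of disease on the biomarker
#' standardized by the analysis sample's SD (cases and controls combined),
#' with optional covariates; Wald 95% confidence interval.
#'
#' @param disease 0/1 vector.
#' @param biomarker numeric vector (standardized internally).
#' @param covariates optional covariate `data.frame`.
#' @param standardize divide the biomarker by its sample SD (default TRUE;
#'   set FALSE for binary or pre-scaled exposures).
#' @return `data.frame` of class `or_estimate` with columns `or`, `ci_low`,
#'   `ci_high`, `log_or`, `se_log_or`, `p`, `n`, `adjusted` (comma-joined
#'   covariate names).
#' @export
logistic_or_per_sd <- function(disease, biomarker, covariates = NULL,
                               standardize = TRUE) {
  keep <- is.finite(biomarker) & !is.na(disease)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- disease[keep]
  x <- biomarker[keep]
  if (standardize) x <- x / stats::sd(x)
  df <- data.frame(y = y, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates[keep, , drop = FALSE])
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  if (!fit$converged) stop("logistic regression did not converge")
  cf <- summary(fit)$coefficients
  b <- cf["x", "Estimate"]; se <- cf["x", "Std. Error"]
  if (abs(b) > 15) stop("separation: logistic estimate diverged")
  out <- data.frame(
    or = exp(b), ci_low = exp(b - 1.959964 * se),
    ci_high = exp(b + 1.959964 * se),
    log_or = b, se_log_or = se, p = cf["x", "Pr(>|z|)"], n = length(y),
    adjusted = if (is.null(covariates)) "" else
      paste(colnames(covariates), collapse = ","))
  class(out) <- c("or_estimate", "data.frame")
  out
}

#' Two-sample power for a standardized mean difference
#'
#' Two-sided normal-approximation power to detect a difference of `delta_sd`
#' standard deviations between groups of size `n1` and `n2` at level
#' `alpha`: `Phi(|d|/SE - z) + Phi(-|d|/SE - z)` with
#' `SE = sqrt(1/n1 + 1/n2)` and `z = qnorm(1 - alpha/2)`.
#'
#' @param n1,n2 group sizes.
#' @param delta_sd true difference in SD units.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
two_sample_power <- function(n1, n2, delta_sd, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  se <- sqrt(1 / n1 + 1 / n2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(delta_sd) / se - z) + stats::pnorm(-abs(delta_sd) / se - z)
}

#' Partial correlation of two variables given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates, with a Fisher-z 95% confidence interval and
#' a t-test p-value using `n - k - 2` degrees of freedom (k covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates covariate `data.frame` (may be NULL for the plain
#'   correlation).
#' @return list with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 3) stop("too few observations")
  if (!is.null(covariates)) {
    M <- stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
    x <- stats::lm.fit(M, x)$residuals
    y <- stats::lm.fit(M, y)$residuals
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero residual variance")
  r <- stats::cor(x, y)
  z <- atanh(r)
  se_z <- 1 / sqrt(n - k - 3)
  tstat <- r * sqrt((n - k - 2) / (1 - r^2))
  list(r = r, ci_low = tanh(z - 1.959964 * se_z),
       ci_high = tanh(z + 1.959964 * se_z),
       p = 2 * stats::pt(-abs(tstat), df = n - k - 2), n = n)
}
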