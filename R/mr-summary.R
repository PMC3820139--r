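# split-chain potential scale reduction factor (R-hat)
split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  Bv <- nn * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + Bv / nn) / W)
}

# effective sample size via Geyer's initial monotone positive sequence on
# chain-demeaned draws
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  x <- sweep(mat, 2, colMeans(mat))
  v <- mean(apply(mat, 2, stats::var))
  if (v <= 0) return(n * m)
  max_lag <- min(n - 2, 200)
  rho <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    rho[k + 1] <- mean(vapply(seq_len(m), function(ch) {
      mean(x[seq_len(n - k), ch] * x[(k + 1):n, ch])
    }, 0)) / v
  }
  tau <- 1
  k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho[k + 1] + rho[k + 2]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}

#' Posterior summaries with convergence diagnostics
#'
#' Per-parameter posterior mean, median, central 95% credible interval,
#' split R-hat and effective sample size. Log-odds-ratio parameters (the
#' causal effects `theta_*`, the direct effects `delta_*`) also get
#' exponentiated odds-ratio columns whose interval endpoints are the
#' exponentials of the log-scale endpoints. A convergence warning flag is
#' set if any causal or direct effect has R-hat above 1.05.
#'
#' @param fit an `iv_draws` object from [run_mcmc()].
#' @param min_draws smallest acceptable number of post-warmup draws per
#'   chain.
#' @return `data.frame` of class `posterior_summary`, one row per parameter,
#'   with `attr(, "convergence_warning")`.
#' @export
summarize_posterior <- function(fit, min_draws = 200) {
  stopifnot(inherits(fit, "iv_draws"))
  if (dim(fit$draws)[2] < 2 || dim(fit$draws)[1] < min_draws) {
    stop("need at least 2 chains with ", min_draws, " post-warmup draws")
  }
  pars <- fit$par_names
  out <- data.frame(parameter = pars, mean = NA_real_, median = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_, rhat = NA_real_,
                    ess = NA_real_, or = NA_real_, or_low = NA_real_,
                    or_high = NA_real_, stringsAsFactors = FALSE)
  is_lor <- grepl("^(theta_|delta_)", pars)
  for (i in seq_along(pars)) {
    mat <- fit$draws[, , i]
    v <- as.vector(mat)
    out$mean[i] <- mean(v)
    out$median[i] <- stats::median(v)
    out$q2.5[i] <- stats::quantile(v, 0.025, names = FALSE)
    out$q97.5[i] <- stats::quantile(v, 0.975, names = FALSE)
    out$rhat[i] <- if (stats::sd(v) > 0) split_rhat(mat) else 1
    out$ess[i] <- ess_basic(mat)
    if (is_lor[i]) {
      out$or[i] <- exp(out$mean[i])
      out$or_low[i] <- exp(out$q2.5[i])
      out$or_high[i] <- exp(out$q97.5[i])
    }
  }
  headline <- is_lor
  warn <- any(out$rhat[headline] > 1.05, na.rm = TRUE)
  if (warn) {
    warning("convergence warning: R-hat > 1.05 on a causal or direct effect")
  }
  attr(out, "convergence_warning") <- warn
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (", nrow(x), " parameters)",
      if (attr(x, "convergence_warning")) "  [CONVERGENCE WARNING]", "\n",
      sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' Observational versus causal odds ratios, side by side
#'
#' For each biomarker, pairs the observational covariate-adjusted odds ratio
#' per SD (logistic regression in the exposure+outcome cohort, adjusting for
#' age, sex and the other biomarker) with the causal posterior odds ratio
#' per SD from the instrumental-variable fit, and flags whether the two
#' agree in direction and whether each excludes the null. Divergence between
#' the columns is the signature of non-causal associations (e.g. a
#' post-onset shift in the measured biomarker).
#'
#' @param bundle the `cohort_bundle` analysed.
#' @param summary a [summarize_posterior()] result.
#' @param cohort name of the exposure+outcome cohort.
#' @param exposures biomarker column names.
#' @return `data.frame` with one row per biomarker: observational OR and CI,
#'   causal OR and CI, and concordance flags.
#' @export
observational_vs_causal_report <- function(bundle, summary,
                                           cohort = "casecontrol_bio",
                                           exposures = c("cfh", "cfhr1")) {
  co <- bundle$cohorts[[cohort]]
  if (is.null(co$biomarkers) || is.null(co$disease)) {
    stop("cohort must carry both biomarkers and disease status")
  }
  rows <- list()
  for (ex in exposures) {
    other <- setdiff(exposures, ex)
    covar <- cbind(co$covariates[, c("age", "sex")],
                   stats::setNames(co$biomarkers[other], other))
    obs <- logistic_or_per_sd(co$disease, co$biomarkers[[ex]], covar)
    srow <- summary[summary$parameter == paste0("theta_", ex), ]
    rows[[ex]] <- data.frame(
      biomarker = ex,
      obs_or = obs$or, obs_low = obs$ci_low, obs_high = obs$ci_high,
      causal_or = srow$or, causal_low = srow$or_low,
      causal_high = srow$or_high,
      direction_concordant = sign(log(obs$or)) == sign(log(srow$or)),
      obs_excludes_null = obs$ci_low > 1 | obs$ci_high < 1,
      causal_excludes_null = srow$or_low > 1 | srow$or_high < 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
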