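#' Additive single-locus linear association
#'
#' Ordinary least squares of a quantitative trait on minor-allele dosage plus
#' covariates. The reported effect is the dosage coefficient (trait units per
#' allele); `r` is the Pearson correlation of the dosage with the
#' covariate-adjusted trait; `var_explained` is `beta^2 Var(g) / Var(y)` on
#' the raw trait scale and `var_explained_adj` the same fraction of the
#' covariate-adjusted trait variance (both are reported because "variance
#' explained" is quoted on either scale in practice).
#'
#' @param trait numeric trait vector.
#' @param dosage numeric dosage vector (0/1/2, `NA` dropped pairwise).
#' @param covariates optional `data.frame` of covariates.
#' @param locus label for the output row.
#' @return one-row `data.frame` of class `assoc_result` with columns `locus`,
#'   `beta`, `se`, `p`, `r`, `var_explained`, `var_explained_adj`, `n`.
#' @export
fit_additive_linear <- function(trait, dosage, covariates = NULL,
                                locus = "locus") {
  keep <- is.finite(trait) & is.finite(dosage)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- trait[keep]; g <- dosage[keep]
  n <- length(y)
  if (stats::var(g) == 0) stop("zero-variance (monomorphic) dosage")
  X <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
  }
  if (n <= ncol(X) + 1L) stop("too few observations for the design")
  M <- cbind(X, g = g)
  if (qr(M)$rank < ncol(M)) stop("rank-deficient design (collinearity)")
  fit <- stats::lm.fit(M, y)
  rdf <- n - ncol(M)
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- solve(crossprod(M))
  beta <- fit$coefficients[["g"]]
  se <- sqrt(XtXinv["g", "g"] * sigma2)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), rdf)
  # dosage correlation with the covariate-adjusted trait
  y_adj <- if (ncol(X) > 1L) stats::lm.fit(X, y)$residuals else y - mean(y)
  r <- stats::cor(g, y_adj)
  ve_raw <- beta^2 * stats::var(g) / stats::var(y)
  ve_adj <- beta^2 * stats::var(g) / stats::var(y_adj + 0)  # adjusted scale
  out <- data.frame(locus = locus, beta = beta, se = se, p = p, r = r,
                    var_explained = ve_raw, var_explained_adj = ve_adj,
                    n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' REML fit of the null polygenic mixed model
#'
#' Fits `y = X b + a + e` with `a ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood, using a single
#' eigendecomposition of the kinship matrix and one-dimensional optimization
#' of the profiled restricted log-likelihood over `h2 = sigma2_g /
#' (sigma2_g + sigma2_e)`. The rotation and variance components are cached
#' for score tests.
#'
#' @param trait numeric trait vector.
#' @param covariates optional covariate `data.frame` (fixed effects).
#' @param kinship additive relationship matrix (2 * kinship, PSD).
#' @param eigen_k optional precomputed `eigen(kinship, symmetric = TRUE)`;
#'   supplying it lets many traits reuse one decomposition.
#' @return object of class `polygenic_null` with elements `h2`, `se_h2`,
#'   `sigma2_g`, `sigma2_e`, `fixef`, `loglik`, `boundary`, plus cached
#'   rotation for [mmscore_scan()].
#' @export
fit_polygenic_null <- function(trait, covariates = NULL, kinship,
                               eigen_k = NULL) {
  n <- length(trait)
  stopifnot(nrow(kinship) == n)
  if (max(abs(kinship - diag(n))) < 1e-10) {
    stop("kinship is the identity: polygenic and environmental components are not identifiable")
  }
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = covariates)
  if (is.null(eigen_k)) eigen_k <- eigen(kinship, symmetric = TRUE)
  lambda <- pmax(eigen_k$values, 0)
  U <- eigen_k$vectors
  yt <- drop(crossprod(U, trait))
  Xt <- crossprod(U, X)
  p <- ncol(X)

  restricted_ll <- function(h2) {
    w <- h2 * lambda + (1 - h2)
    wi <- 1 / w
    XtW <- Xt * wi
    A <- crossprod(XtW, Xt)
    b <- solve(A, crossprod(XtW, yt))
    res <- yt - Xt %*% b
    rss <- sum(res^2 * wi)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              determinant(A, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(restricted_ll, interval = c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  ll <- opt$objective
  boundary <- FALSE
  for (hb in c(0, 1)) {
    llb <- restricted_ll(min(max(hb, 1e-9), 1 - 1e-9))
    if (llb > ll) { h2 <- hb; ll <- llb; boundary <- TRUE }
  }
  if (h2 < 5e-6 || h2 > 1 - 5e-6) boundary <- TRUE

  # SE from the curvature of the restricted log-likelihood
  eps <- 1e-4
  h2c <- min(max(h2, eps), 1 - eps)
  curv <- (restricted_ll(h2c + eps) - 2 * restricted_ll(h2c) +
             restricted_ll(h2c - eps)) / eps^2
  se_h2 <- if (is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_

  h2e <- min(max(h2, 1e-9), 1 - 1e-9)
  w <- h2e * lambda + (1 - h2e)
  wi <- 1 / w
  XtW <- Xt * wi
  A <- crossprod(XtW, Xt)
  b <- solve(A, crossprod(XtW, yt))
  res <- yt - Xt %*% b
  s2_tot <- sum(res^2 * wi) / (n - p)
  structure(list(
    h2 = h2, se_h2 = se_h2, boundary = boundary,
    sigma2_g = h2 * s2_tot, sigma2_e = (1 - h2) * s2_tot,
    sigma2_total = s2_tot,
    fixef = drop(b), loglik = ll,
    U = U, lambda = lambda, w = w, Xt = Xt, yt = yt,
    resid_rot = drop(res), X = X
  ), class = "polygenic_null")
}

#' @export
print.polygenic_null <- function(x, ...) {
  cat(sprintf("Polygenic null model: h2 = %.3f (SE %.3f)%s, sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$h2, x$se_h2, if (x$boundary) " [boundary]" else "",
              x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Mixed-model score test scan over loci (mmscore)
#'
#' For each locus, computes the score statistic
#' `T = (g~' V^-1 r)^2 / (g~' V^-1 g~)` where `V = sigma2_g K + sigma2_e I`
#' from the null polygenic fit, `r` are the null-model GLS residuals and `g~`
#' the covariate-adjusted dosage; `p` is from a 1-df chi-square. The reported
#' effect is the one-step score-based estimate
#' `beta = g~' V^-1 r / (g~' V^-1 g~)`.
#'
#' @param dosages dosage matrix (individuals x loci). Missing entries are
#'   mean-imputed per locus for the test (rates are low by design).
#' @param null_fit a [fit_polygenic_null()] object fitted on the same
#'   individuals (same trait and covariates).
#' @return `data.frame` of class `assoc_result`, one row per testable locus;
#'   monomorphic loci are skipped and listed in `attr(, "skipped")`.
#' @export
mmscore_scan <- function(dosages, null_fit) {
  stopifnot(inherits(null_fit, "polygenic_null"))
  wi <- 1 / (null_fit$w * null_fit$sigma2_total)   # diag of V^-1 in rotated space
  r <- null_fit$resid_rot
  Xt <- null_fit$Xt
  skipped <- character()
  rows <- list()
  for (j in seq_len(ncol(dosages))) {
    g <- dosages[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::var(g) == 0) {
      skipped <- c(skipped, colnames(dosages)[j])
      next
    }
    gt <- drop(crossprod(null_fit$U, g))
    # GLS-adjust dosage for fixed effects
    XtW <- Xt * wi
    A <- crossprod(XtW, Xt)
    coef_g <- solve(A, crossprod(XtW, gt))
    gtil <- gt - Xt %*% coef_g
    num <- sum(gtil * wi * r)
    den <- sum(gtil^2 * wi)
    beta <- num / den
    se <- sqrt(1 / den)
    T <- num^2 / den
    rows[[length(rows) + 1L]] <- data.frame(
      locus = colnames(dosages)[j], beta = beta, se = se,
      p = stats::pchisq(T, df = 1, lower.tail = FALSE),
      r = NA_real_, var_explained = NA_real_, var_explained_adj = NA_real_,
      n = length(g), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-locus linear association scan
#'
#' Runs [fit_additive_linear()] for every polymorphic locus of a dosage
#' matrix against one trait.
#'
#' @param trait numeric trait vector.
#' @param dosages dosage matrix.
#' @param covariates optional covariate `data.frame`.
#' @return `assoc_result` data.frame with one row per testable locus;
#'   skipped loci (monomorphic or collinear) in `attr(, "skipped")`.
#' @export
assoc_scan <- function(trait, dosages, covariates = NULL) {
  rows <- list(); skipped <- character()
  for (j in seq_len(ncol(dosages))) {
    res <- tryCatch(
      fit_additive_linear(trait, dosages[, j], covariates,
                          locus = colnames(dosages)[j]),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, colnames(dosages)[j])
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Conditional association scan
#'
#' Re-runs the per-locus scan with the dosage of one adjustment locus
#' appended to the covariates; the adjustment locus itself is excluded from
#' the output. If an association signal is entirely driven by LD with the
#' adjustment locus, its peak disappears in this scan.
#'
#' @param trait numeric trait vector.
#' @param dosages dosage matrix including the adjustment locus.
#' @param covariates optional covariate `data.frame`.
#' @param adjust_locus column name of the locus to condition on.
#' @return `assoc_result` data.frame without the adjustment locus; loci
#'   skipped (e.g. perfectly collinear with the adjustment locus) in
#'   `attr(, "skipped")`.
#' @export
conditional_scan <- function(trait, dosages, covariates = NULL, adjust_locus) {
  stopifnot(adjust_locus %in% colnames(dosages))
  g_adj <- dosages[, adjust_locus]
  if (anyNA(g_adj)) g_adj[is.na(g_adj)] <- mean(g_adj, na.rm = TRUE)
  if (stats::var(g_adj) == 0) stop("adjustment locus is monomorphic")
  cov2 <- if (is.null(covariates)) data.frame(adj_dosage = g_adj) else
    cbind(covariates, adj_dosage = g_adj)
  keep <- setdiff(colnames(dosages), adjust_locus)
  assoc_scan(trait, dosages[, keep, drop = FALSE], cov2)
}
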