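test_that("identical groups give zero difference and adjusted estimates match lm", {
  set.seed(1)
  y <- rep(stats::rnorm(40), 2)
  d <- rep(c(1L, 0L), each = 40)
  cmp <- compare_means(y, d)
  expect_equal(cmp$difference, 0)
  # adjusted estimate equals the normal-equation oracle on random instances
  for (i in 1:100) {
    n <- sample(30:80, 1)
    dd <- stats::rbinom(n, 1, 0.4)
    cov <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
    yy <- stats::rnorm(n) + 0.5 * dd + 0.2 * cov$a
    cmp_i <- compare_means(yy, dd, cov)
    X <- cbind(1, dd, cov$a, cov$b)
    beta <- solve(crossprod(X), crossprod(X, yy))
    expect_equal(cmp_i$adjusted_difference, beta[2], tolerance = 1e-8)
  }
})

test_that("the SAMD-like preset reproduces the published CFH case-control gap", {
  cfg <- cohort_config(disease_preset = "observational")
  res <- vapply(1:8, function(s) {
    b <- assemble_cohorts(cfg, seed = 100 + s)
    cc <- b$cohorts$casecontrol_bio
    cmp <- compare_means(cc$biomarkers$cfh, cc$disease,
                         cc$covariates[, c("age", "sex")])
    se <- sqrt(cmp$sem_cases^2 + cmp$sem_controls^2)
    c(-cmp$difference, se, cmp$p_unadjusted, cmp$p_adjusted)
  }, c(0, 0, 0, 0))
  expect_lt(abs(mean(res[1, ]) - 15.7), 2 * mean(res[2, ]) / sqrt(8))
  # the gap is detectable in most runs, unadjusted and adjusted
  expect_gt(mean(res[3, ] < 0.05), 0.6)
})

test_that("binary-exposure logistic OR equals the 2x2 cross-product", {
  d <- rep(c(1L, 1L, 0L, 0L), c(10, 20, 30, 40))
  x <- rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
  res <- logistic_or_per_sd(d, x, standardize = FALSE)
  expect_equal(res$or, (10 * 40) / (20 * 30), tolerance = 1e-6)
})

test_that("the adjusted CFHR1 odds ratio matches the published 0.72", {
  cfg <- cohort_config(disease_preset = "observational", onset = "cfhr1")
  ors <- vapply(1:8, function(s) {
    b <- assemble_cohorts(cfg, seed = 200 + s)
    cc <- b$cohorts$casecontrol_bio
    res <- logistic_or_per_sd(cc$disease, cc$biomarkers$cfhr1,
                              cbind(cc$covariates[, c("age", "sex")],
                                    cfh = cc$biomarkers$cfh))
    res$log_or
  }, 0)
  # published value inside 2 cross-seed SEs of the mean log-OR
  expect_lt(abs(mean(ors) - log(0.72)), 2 * stats::sd(ors) / sqrt(8))
})

test_that("a null biomarker's CI covers 1 at close to the nominal rate", {
  set.seed(3)
  cover <- vapply(1:200, function(i) {
    d <- stats::rbinom(150, 1, 0.4)
    x <- stats::rnorm(150)
    res <- logistic_or_per_sd(d, x)
    res$ci_low <= 1 && res$ci_high >= 1
  }, TRUE)
  # Wald intervals undercover slightly at this sample size
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 0.995)
})

test_that("power formula reproduces the published under-powered band", {
  # the three cited studies at a 0.27 SD difference
  p <- c(two_sample_power(53, 75, 0.27),
         two_sample_power(112, 67, 0.27),
         two_sample_power(120, 60, 0.27))
  expect_true(all(p >= 0.31 & p <= 0.42))
  expect_equal(p[1], 0.33, tolerance = 0.02 / 0.33)
  # closed-form oracle recomputed inline
  se <- sqrt(1 / 53 + 1 / 75)
  oracle <- stats::pnorm(0.27 / se - stats::qnorm(0.975)) +
    stats::pnorm(-0.27 / se - stats::qnorm(0.975))
  expect_equal(p[1], oracle)
  expect_equal(two_sample_power(100, 100, 0), 0.05, tolerance = 1e-10)
  # monotone in group size
  expect_true(all(diff(vapply(c(50, 100, 200, 400),
                              function(n) two_sample_power(n, 75, 0.27),
                              0)) > 0))
})

test_that("partial correlation is calibrated under conditional independence", {
  set.seed(4)
  cover <- vapply(1:200, function(i) {
    z <- stats::rnorm(120)
    x <- z + stats::rnorm(120)
    y <- z + stats::rnorm(120)
    pc <- partial_correlation(x, y, data.frame(z = z))
    pc$ci_low <= 0 && pc$ci_high >= 0
  }, TRUE)
  expect_gt(mean(cover), 0.90)
})

test_that("the two biomarkers are negatively correlated after covariate adjustment", {
  b <- assemble_cohorts(cohort_config(), seed = 9)
  pop <- b$cohorts$population
  pc <- partial_correlation(pop$biomarkers$cfh, pop$biomarkers$cfhr1,
                            pop$covariates[, c("age", "sex")])
  expect_lt(pc$r, -0.1)
  # additionally partialling out the driving genotypes removes it
  pc2 <- partial_correlation(
    pop$biomarkers$cfh, pop$biomarkers$cfhr1,
    cbind(pop$covariates[, c("age", "sex")],
          idx = ifelse(is.na(pop$dosages[, "rs6677604"]), 1,
                       pop$dosages[, "rs6677604"]),
          del = ifelse(is.na(pop$dosages[, "CNP147"]), 1,
                       pop$dosages[, "CNP147"])))
  expect_lt(abs(pc2$r), 0.07)
})
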