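test_that("zero effects and variances give a constant trait at the intercept", {
  m <- two_locus_model()
  co <- unrelated_cohort(50, m, seed = 2)
  p0 <- biomarker_params(intercept = 7, sigma2_poly = 0, sigma2_env = 0)
  bio <- simulate_biomarkers(co$g, co$covar, co$ped,
                             list(a = p0, b = p0), seed = 3)
  expect_equal(bio$a, rep(7, 50))
  expect_equal(bio$b, rep(7, 50))
  expect_error(biomarker_params(0, sigma2_env = -1), "nonnegative")
})

test_that("default CFH preset reproduces the population mean and SD", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  stats_seeds <- vapply(1:10, function(s) {
    co <- unrelated_cohort(1004, m, seed = 40 + s)
    bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 80 + s)
    c(mean(bio$cfh), stats::sd(bio$cfh))
  }, c(0, 0))
  expect_equal(mean(stats_seeds[1, ]), 400, tolerance = 2 / 400)
  expect_equal(mean(stats_seeds[2, ]), 62, tolerance = 2 / 62)
})

test_that("traits with disjoint loci and rho_assay 0 have near-zero residual correlation", {
  m <- default_haplotype_model()
  co <- unrelated_cohort(1000, m, seed = 6)
  pa <- biomarker_params(0, beta = c(rs6677604 = 1), sigma2_env = 1)
  pb <- biomarker_params(0, sigma2_env = 1)
  bio <- simulate_biomarkers(co$g, co$covar, co$ped,
                             list(a = pa, b = pb), seed = 7)
  res_a <- stats::resid(stats::lm(bio$a ~ co$g[, "rs6677604"]))
  expect_lt(abs(stats::cor(res_a, bio$b)), 0.08)
})

test_that("polygenic sampling matches sigma2 * K on a fixed 20-person pedigree", {
  ped <- simulate_pedigrees(n_families = 4, sibship_size = 3)
  K <- kinship_matrix(ped)
  sigma2 <- 2.5
  set.seed(99)
  draws <- replicate(2000, mrtriad:::sample_polygenic(ped, sigma2))
  emp <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  target <- sigma2 * K
  # entrywise MC standard error of a covariance estimate
  mc_se <- sqrt((outer(diag(target), diag(target)) + target^2) / 2000)
  expect_true(all(abs(emp - target) < 3.5 * mc_se))
})

test_that("null disease model hits the requested prevalence", {
  m <- two_locus_model()
  co <- unrelated_cohort(10000, m, seed = 8)
  bio <- data.frame(x = stats::rnorm(10000))
  dp <- disease_params(stats::qlogis(0.1), theta = c(x = 0))
  d <- simulate_disease(bio, co$g, co$covar, dp, c(x = 1), c(x = 0), seed = 9)
  expect_equal(mean(d), 0.10, tolerance = 0.1)
})

test_that("logistic refit on the true standardized biomarker recovers theta", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  tm <- biomarker_truth_moments(m, params)
  co <- unrelated_cohort(20000, m, seed = 10)
  bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 11)
  dp <- disease_params(stats::qlogis(0.1), theta = c(cfh = log(0.52), cfhr1 = 0))
  d <- simulate_disease(bio, co$g, co$covar, dp, tm$sd, tm$mean, seed = 12)
  x_std <- (bio$cfh - tm$mean[["cfh"]]) / tm$sd[["cfh"]]
  fit <- stats::glm(d ~ x_std + I((bio$cfhr1 - tm$mean[["cfhr1"]]) / tm$sd[["cfhr1"]]),
                    family = stats::binomial())
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf["x_std", "Estimate"] - log(0.52)),
            2 * cf["x_std", "Std. Error"])
})

test_that("stronger causal effects widen the case-control biomarker gap", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  tm <- biomarker_truth_moments(m, params)
  gaps <- vapply(c(-0.33, -0.66), function(th) {
    mean(vapply(1:3, function(s) {
      co <- unrelated_cohort(6000, m, seed = 20 + s)
      bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 30 + s)
      dp <- disease_params(stats::qlogis(0.1), theta = c(cfh = th, cfhr1 = 0))
      d <- simulate_disease(bio, co$g, co$covar, dp, tm$sd, tm$mean,
                            seed = 40 + s)
      mean(bio$cfh[d == 0]) - mean(bio$cfh[d == 1])
    }, 0))
  }, 0)
  expect_gt(gaps[2], gaps[1])
})

test_that("onset shift moves exactly the affected rows and preserves latents", {
  bio <- data.frame(cfh = c(1, 2, 3, 4), cfhr1 = c(5, 6, 7, 8))
  d <- c(0L, 1L, 1L, 0L)
  out <- apply_onset_shift(bio, d, c(cfhr1 = -0.5))
  expect_equal(out$cfh, bio$cfh)
  expect_equal(out$cfhr1, bio$cfhr1 - 0.5 * d)
  expect_equal(sum(out$cfhr1 != bio$cfhr1), sum(d))
  expect_equal(apply_onset_shift(bio, d, c(cfhr1 = 0)), bio)
})

test_that("cases show lower measured CFHR1 despite higher genotype-predicted values", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  tm <- biomarker_truth_moments(m, params)
  dp <- preset_disease_params("observational", tm)
  shift <- preset_onset_shift(m, params)
  co <- unrelated_cohort(40000, m, seed = 31)
  bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 32)
  d <- simulate_disease(bio, co$g, co$covar, dp, tm$sd, tm$mean, seed = 33)
  measured <- apply_onset_shift(bio, d, shift)
  # measured values: cases lower (the onset shift dominates)
  expect_lt(mean(measured$cfhr1[d == 1]), mean(measured$cfhr1[d == 0]))
  # genotype-predicted values: cases higher (the deletion is depleted in
  # cases through LD with the CFH-raising allele, and lowers CFHR1)
  pred <- params$cfhr1$beta[["CNP147"]] * co$g[, "CNP147"]
  expect_gt(mean(pred[d == 1]), mean(pred[d == 0]))
})

test_that("with no causal effect and no onset shift, case and control biomarkers are exchangeable", {
  m <- two_locus_model()
  dp <- disease_params(stats::qlogis(0.3), theta = c(x = 0))
  pvals <- vapply(1:50, function(s) {
    co <- unrelated_cohort(400, m, seed = 4000 + s)
    bio <- data.frame(x = with_seed(4100 + s, stats::rnorm(400, 10, 2)))
    d <- simulate_disease(bio, co$g, co$covar, dp, c(x = 2), c(x = 10),
                          seed = 4200 + s)
    suppressWarnings(stats::ks.test(bio$x[d == 1], bio$x[d == 0])$p.value)
  }, 0)
  # calibrated: about 5% of KS tests reject at the 5% level
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.08)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("case-control sampling returns exact counts, errors when short, and is reproducible", {
  d <- rep(c(1L, 0L), c(300, 700))
  s1 <- sample_case_control(d, 100, 200, seed = 5)
  expect_equal(sum(d[s1[1:100]]), 100)
  expect_equal(sum(d[s1[101:300]]), 0)
  expect_identical(s1, sample_case_control(d, 100, 200, seed = 5))
  expect_error(sample_case_control(d, 400, 10, seed = 5), "cases")
})
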