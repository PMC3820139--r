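test_that("covariate-free OLS equals the closed-form two-variable formula", {
  y <- c(1, 2, 3, 4); g <- c(0, 1, 1, 2)
  res <- fit_additive_linear(y, g)
  beta_oracle <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  expect_equal(res$beta, beta_oracle)
  expect_equal(res$beta, 1.5)
  # 100 random small instances against the same closed form
  set.seed(1)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    gg <- stats::rbinom(n, 2, 0.4)
    if (stats::var(gg) == 0) next
    yy <- stats::rnorm(n) + 0.3 * gg
    expect_equal(fit_additive_linear(yy, gg)$beta,
                 sum((gg - mean(gg)) * (yy - mean(yy))) / sum((gg - mean(gg))^2),
                 tolerance = 1e-10)
  }
})

test_that("monomorphic dosage and collinear designs raise errors", {
  expect_error(fit_additive_linear(rnorm(10), rep(1, 10)), "monomorphic")
  g <- rbinom(30, 2, 0.5)
  expect_error(fit_additive_linear(rnorm(30), g,
                                   data.frame(a = g, b = rnorm(30))),
               "collinear")
})

test_that("index-SNP effect on CFH is recovered within 2 SE at n = 1004", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  res <- vapply(1:5, function(s) {
    co <- unrelated_cohort(1004, m, seed = 100 + s)
    bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 200 + s)
    a <- fit_additive_linear(bio$cfh, co$g[, "rs6677604"], co$covar)
    c(a$beta, a$se)
  }, c(0, 0))
  expect_lt(abs(mean(res[1, ]) - 25.6), 2 * mean(res[2, ]) / sqrt(5))
})

test_that("var_explained equals the R-squared increase from adding the SNP", {
  set.seed(3)
  g <- stats::rbinom(300, 2, 0.3)
  y <- 0.5 * g + stats::rnorm(300)
  res <- fit_additive_linear(y, g)
  r2_full <- summary(stats::lm(y ~ g))$r.squared
  expect_equal(res$var_explained, r2_full, tolerance = 1e-6)
})

test_that("mmscore with identity-like kinship matches the linear score test", {
  set.seed(4)
  n <- 400
  # two tiny families so the kinship is not exactly the identity
  ped <- simulate_pedigrees(n_families = 2, sibship_size = 2,
                            n_unrelated = n - 8)
  K <- kinship_matrix(ped)
  K[K != 1 & K != 0] <- 1e-6 * K[K != 1 & K != 0]
  y <- stats::rnorm(n)
  covar <- data.frame(a = stats::rnorm(n))
  g <- cbind(snp = stats::rbinom(n, 2, 0.3))
  null <- fit_polygenic_null(y, covar, K)
  sc <- mmscore_scan(g, null)
  lmfit <- stats::lm(y ~ a + snp, data = data.frame(a = covar$a, snp = g[, 1]))
  p_lm <- summary(lmfit)$coefficients["snp", "Pr(>|t|)"]
  expect_equal(sc$p, p_lm, tolerance = 0.02)
})

test_that("mmscore null p-values are calibrated and uniform in a related cohort", {
  # 300 unlinked null loci transmitted through sibships
  loci <- locus_table(c("idx", paste0("L", 1:300)),
                      rep("snp", 301), rep(0.3, 301),
                      c("index_regulatory", rep("neutral", 300)))
  m <- build_haplotype_model(loci)
  ped <- simulate_pedigrees(n_families = 100, sibship_size = 3)
  K <- kinship_matrix(ped)
  set.seed(5)
  g <- simulate_genotypes(m, ped, seed = 6)
  y <- mrtriad:::sample_polygenic(ped, 1) + stats::rnorm(nrow(ped))
  null <- fit_polygenic_null(y, NULL, K)
  sc <- mmscore_scan(g[, -1], null)
  hit <- mean(sc$p < 0.05)
  expect_lt(abs(hit - 0.05), 2.58 * sqrt(0.05 * 0.95 / 300) + 0.01)
  expect_gt(stats::ks.test(sc$p, "punif")$p.value, 0.01)
})

test_that("index SNP attains the minimum mmscore p in the population scan", {
  b <- assemble_cohorts(cohort_config(missing_rate = 0), seed = 17)
  pop <- b$cohorts$population
  null <- fit_polygenic_null(pop$biomarkers$cfh, pop$covariates, pop$kinship)
  sc <- mmscore_scan(pop$dosages, null)
  expect_equal(sc$locus[which.min(sc$p)], "rs6677604")
})

test_that("conditioning on the causal locus removes the LD peaks", {
  m <- default_haplotype_model()
  params <- default_params_pair()
  worst <- vapply(1:5, function(s) {
    co <- unrelated_cohort(1004, m, seed = 300 + s)
    bio <- simulate_biomarkers(co$g, co$covar, co$ped, params, seed = 400 + s)
    sc <- conditional_scan(bio$cfh, co$g, co$covar, "rs6677604")
    expect_false("rs6677604" %in% sc$locus)
    min(sc$p)
  }, 0)
  expect_gt(mean(worst > 1e-4), 0.7)
})

test_that("adjusting for an unlinked neutral locus leaves the index effect unchanged", {
  loci <- locus_table(c("idx", "far"), c("snp", "snp"), c(0.25, 0.3),
                      c("index_regulatory", "neutral"))
  m <- build_haplotype_model(loci)   # r2 = 0, unlinked
  co <- unrelated_cohort(1500, m, seed = 12)
  y <- 2 * co$g[, "idx"] + stats::rnorm(1500)
  plain <- fit_additive_linear(y, co$g[, "idx"])
  cond <- conditional_scan(y, co$g, NULL, "far")
  expect_lt(abs(cond$beta[cond$locus == "idx"] - plain$beta), 0.5 * plain$se)
})
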