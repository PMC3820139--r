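test_that("model construction validates the spec and counts parameters", {
  expect_error(iv_model_spec(instruments = c("a"), pleiotropy = c("a")),
               "disjoint")
  b <- small_iv_bundle(n = 400, seed = 1)
  model <- build_iv_model(b, cohorts = "cc")
  # closed-form tally: 2 exposures x (1 intercept + 5 loci + 2 covariates)
  # + 3 covariance parameters + (1 cohort intercept + 2 causal + 3 direct +
  # 2 covariate) outcome coefficients
  expect_equal(n_parameters(model), 2 * (1 + 5 + 2) + 3 + (1 + 2 + 3 + 2))
  fit <- run_mcmc(model, n_chains = 2, n_iter = 40, n_warmup = 40, seed = 2)
  expect_equal(length(fit$par_names), n_parameters(model))
  expect_error(run_mcmc(model, n_chains = 1), "n_chains")
})

test_that("a cohort without exposures or outcome is rejected", {
  b <- small_iv_bundle(n = 200, seed = 3)
  b$cohorts$cc$biomarkers <- NULL
  b$cohorts$cc$disease <- NULL
  expect_error(build_iv_model(b, cohorts = "cc"), "neither")
})

test_that("an outcome-only cohort contributes one latent exposure pair per individual", {
  b <- small_iv_bundle(n = 300, seed = 4)
  b$cohorts$go <- b$cohorts$cc
  b$cohorts$go$biomarkers <- NULL
  b$cohorts$go$role <- "outcome_only"
  model <- build_iv_model(b, cohorts = c("cc", "go"))
  fl <- mrtriad:::flatten_iv_model(model)
  expect_equal(length(fl$lat_idx), 300)
  expect_true(all(fl$lat_idx > 300))
})

test_that("draws are reproducible given the seed", {
  b <- small_iv_bundle(n = 300, seed = 5)
  model <- build_iv_model(b, cohorts = "cc")
  f1 <- run_mcmc(model, n_chains = 2, n_iter = 50, n_warmup = 50, seed = 7)
  f2 <- run_mcmc(model, n_chains = 2, n_iter = 50, n_warmup = 50, seed = 7)
  expect_identical(f1$draws, f2$draws)
})

test_that("gaussian-outcome posterior means agree with two-stage least squares", {
  # exposures measured in one cohort, outcome (identity link) in another:
  # the causal coefficients are identified purely through the instruments,
  # so two-sample 2SLS is the classical oracle
  loci <- locus_table(c("A", "B"), c("snp", "snp"), c(0.3, 0.3),
                      c("index_regulatory", "neutral"))
  m <- build_haplotype_model(loci, data.frame(locus = "B", r2 = 0.05))
  mk <- function(n, seed) {
    co <- unrelated_cohort(n, m, seed)
    pA <- biomarker_params(0, beta = c(A = 1), sigma2_env = 1)
    pB <- biomarker_params(0, beta = c(B = 1), sigma2_env = 1)
    bio <- simulate_biomarkers(co$g, co$covar, co$ped,
                               list(x1 = pA, x2 = pB), seed = seed + 2)
    c(co, list(bio = bio))
  }
  e <- mk(2000, 100); o <- mk(2000, 200)
  sd1 <- stats::sd(e$bio$x1); sd2 <- stats::sd(e$bio$x2)
  with_seed(300, {
    y <- -0.5 * (o$bio$x1 / sd1) + 0.25 * (o$bio$x2 / sd2) +
      stats::rnorm(2000)
  })
  b <- list(cohorts = list(
    expo = list(role = "exposure_only", dosages = e$g, covariates = e$covar,
                biomarkers = e$bio, disease = NULL, kinship = NULL),
    out = list(role = "outcome_only", dosages = o$g, covariates = o$covar,
               biomarkers = NULL, disease = y, kinship = NULL)), model = m)
  spec <- iv_model_spec(instruments = c("A", "B"),
                        pleiotropy = character(0), exposures = c("x1", "x2"))
  iv <- build_iv_model(b, spec, cohorts = c("expo", "out"),
                       outcome_family = "gaussian")
  fit <- run_mcmc(iv, n_chains = 2, n_iter = 1000, n_warmup = 800, seed = 5)
  ps <- suppressWarnings(summarize_posterior(fit))

  Z1 <- scale(as.matrix(e$covar[, c("age", "sex")]))
  Z2 <- scale(as.matrix(o$covar[, c("age", "sex")]))
  f1 <- stats::lm(I(e$bio$x1 / sd1) ~ e$g[, "A"] + e$g[, "B"] + Z1)
  f2 <- stats::lm(I(e$bio$x2 / sd2) ~ e$g[, "A"] + e$g[, "B"] + Z1)
  x1h <- cbind(1, o$g[, "A"], o$g[, "B"], Z2) %*% stats::coef(f1)
  x2h <- cbind(1, o$g[, "A"], o$g[, "B"], Z2) %*% stats::coef(f2)
  stage2 <- stats::lm(y ~ x1h + x2h + Z2)
  cf <- summary(stage2)$coefficients
  for (k in 1:2) {
    par <- paste0("theta_", c("x1", "x2"))[k]
    est <- ps$mean[ps$parameter == par]
    mcse <- stats::sd(fit$draws[, , par]) / sqrt(ps$ess[ps$parameter == par])
    tol <- 3 * mcse + 0.5 * cf[k + 1, "Std. Error"]
    expect_lt(abs(est - cf[k + 1, "Estimate"]), tol)
  }
})

test_that("null causal effects are covered by the credible interval at the nominal rate", {
  cover <- vapply(1:20, function(s) {
    b <- small_iv_bundle(n = 700, seed = 100 + s,
                         theta = c(cfh = 0, cfhr1 = 0))
    model <- build_iv_model(b, cohorts = "cc")
    fit <- run_mcmc(model, n_chains = 2, n_iter = 350, n_warmup = 300,
                    seed = s)
    ps <- suppressWarnings(summarize_posterior(fit, min_draws = 300))
    row <- ps[ps$parameter == "theta_cfh", ]
    row$q2.5 <= 0 && row$q97.5 >= 0
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("omitting the pleiotropy loci biases the causal effect, restoring them removes it", {
  # the bias flows through the marginal genotype-outcome association, so use
  # an exposure cohort plus an outcome-only cohort, with a pleiotropic locus
  # in strong LD with the instrument of the first exposure
  loci <- locus_table(c("A", "B", "P"), rep("snp", 3), c(0.3, 0.3, 0.3),
                      c("index_regulatory", "neutral", "pleiotropic"))
  m <- build_haplotype_model(loci, data.frame(locus = c("B", "P"),
                                              r2 = c(0.05, 0.4)))
  mk <- function(n, seed) {
    co <- unrelated_cohort(n, m, seed)
    pA <- biomarker_params(0, beta = c(A = 1), sigma2_env = 1)
    pB <- biomarker_params(0, beta = c(B = 1), sigma2_env = 1)
    bio <- simulate_biomarkers(co$g, co$covar, co$ped,
                               list(x1 = pA, x2 = pB), seed = seed + 2)
    c(co, list(bio = bio))
  }
  e <- mk(2000, 155); o <- mk(3000, 166)
  with_seed(177, {
    y <- -0.5 * o$bio$x1 / stats::sd(e$bio$x1) +
      0.5 * (o$g[, "P"] - 0.6) + stats::rnorm(3000)
  })
  b <- list(cohorts = list(
    expo = list(role = "exposure_only", dosages = e$g, covariates = e$covar,
                biomarkers = e$bio, disease = NULL, kinship = NULL),
    out = list(role = "outcome_only", dosages = o$g, covariates = o$covar,
               biomarkers = NULL, disease = y, kinship = NULL)), model = m)
  spec_full <- iv_model_spec(instruments = c("A", "B"), pleiotropy = "P",
                             exposures = c("x1", "x2"))
  spec_nople <- iv_model_spec(instruments = c("A", "B"),
                              pleiotropy = character(0),
                              exposures = c("x1", "x2"))
  fit_full <- run_mcmc(build_iv_model(b, spec_full,
                                      cohorts = c("expo", "out"),
                                      outcome_family = "gaussian"),
                       n_chains = 2, n_iter = 800, n_warmup = 700, seed = 57)
  fit_nople <- run_mcmc(build_iv_model(b, spec_nople,
                                       cohorts = c("expo", "out"),
                                       outcome_family = "gaussian"),
                        n_chains = 2, n_iter = 800, n_warmup = 700, seed = 58)
  th_full <- suppressWarnings(summarize_posterior(fit_full))
  th_nople <- suppressWarnings(summarize_posterior(fit_nople))
  est_full <- th_full$mean[th_full$parameter == "theta_x1"]
  est_nople <- th_nople$mean[th_nople$parameter == "theta_x1"]
  # the risk-raising pleiotropic allele travels with the instrument's minor
  # allele, so leaving it out drags the causal estimate toward risk
  expect_gt(est_nople, est_full + 0.15)
  expect_lt(abs(est_full - (-0.5)), 0.15)
})

test_that("adding an outcome-only cohort sharpens the causal posterior", {
  cfg <- cohort_config(n_population = 500, n_cases_bio = 150,
                       n_controls_bio = 150, n_advanced_bio = 150,
                       n_cases_geno = 600, n_controls_geno = 300,
                       missing_rate = 0)
  b <- assemble_cohorts(cfg, seed = 61)
  m_small <- build_iv_model(b, cohorts = c("population", "casecontrol_bio"))
  m_big <- build_iv_model(b, cohorts = c("population", "casecontrol_bio",
                                         "casecontrol_geno"))
  f_small <- run_mcmc(m_small, n_chains = 2, n_iter = 500, n_warmup = 400,
                      seed = 62)
  f_big <- run_mcmc(m_big, n_chains = 2, n_iter = 500, n_warmup = 400,
                    seed = 63)
  sd_small <- stats::sd(f_small$draws[, , "theta_cfh"])
  sd_big <- stats::sd(f_big$draws[, , "theta_cfh"])
  expect_lt(sd_big, sd_small)
})

test_that("the outcome-block posterior matches an independent MCMC engine", {
  # with fully measured exposures and no latents the outcome coefficients
  # factorize from the exposure block, so the same logistic model fitted in
  # JAGS with identical priors and standardization is an exact oracle
  b <- small_iv_bundle(n = 900, seed = 81)
  model <- build_iv_model(b, cohorts = "cc")
  fit <- run_mcmc(model, n_chains = 2, n_iter = 1200, n_warmup = 800,
                  seed = 82)
  ps <- suppressWarnings(summarize_posterior(fit))

  cc <- b$cohorts$cc
  ctrl <- cc$disease == 0
  x1 <- (cc$biomarkers$cfh - mean(cc$biomarkers$cfh[ctrl])) /
    stats::sd(cc$biomarkers$cfh[ctrl])
  x2 <- (cc$biomarkers$cfhr1 - mean(cc$biomarkers$cfhr1[ctrl])) /
    stats::sd(cc$biomarkers$cfhr1[ctrl])
  ple <- c("rs1061170", "rs800292", "rs388862")
  gply <- sweep(cc$dosages[, ple], 2, colMeans(cc$dosages[, ple]))
  za <- scale(cc$covariates$age)
  zs <- scale(cc$covariates$sex)
  dat <- list(d = cc$disease, x1 = x1, x2 = x2,
              g1 = gply[, 1], g2 = gply[, 2], g3 = gply[, 3],
              za = as.vector(za), zs = as.vector(zs), n = length(x1))
  jags_code <- "model {
    for (i in 1:n) {
      d[i] ~ dbern(ilogit(gam + th1*x1[i] + th2*x2[i] +
                          d1*g1[i] + d2*g2[i] + d3*g3[i] +
                          p1*za[i] + p2*zs[i]))
    }
    gam ~ dnorm(0, 0.25); th1 ~ dnorm(0, 0.25); th2 ~ dnorm(0, 0.25)
    d1 ~ dnorm(0, 0.25); d2 ~ dnorm(0, 0.25); d3 ~ dnorm(0, 0.25)
    p1 ~ dnorm(0, 0.25); p2 ~ dnorm(0, 0.25)
  }"
  jm <- rjags::jags.model(textConnection(jags_code), data = dat,
                          n.chains = 2, quiet = TRUE)
  update(jm, 1500)
  sm <- summary(rjags::coda.samples(jm, c("th1", "d1"), 5000))$statistics
  for (pair in list(c("theta_cfh", "th1"), c("delta_rs1061170", "d1"))) {
    ours <- ps[ps$parameter == pair[1], ]
    mcse <- stats::sd(fit$draws[, , pair[1]]) / sqrt(ours$ess)
    expect_lt(abs(ours$mean - sm[pair[2], "Mean"]),
              4 * (mcse + sm[pair[2], "Time-series SE"]) + 0.01)
  }
})

test_that("posterior summaries of constant draws collapse to the constant", {
  draws <- array(2, dim = c(300, 2, 1), dimnames = list(NULL, NULL, "theta_x"))
  fake <- structure(list(draws = draws, par_names = "theta_x",
                         n_iter = 300, n_warmup = 0), class = "iv_draws")
  ps <- summarize_posterior(fake)
  expect_equal(ps$mean, 2)
  expect_equal(ps$median, 2)
  expect_equal(ps$q2.5, 2)
  expect_equal(ps$q97.5, 2)
})

test_that("the observational-vs-causal report reproduces the qualitative dissociation", {
  cfg <- cohort_config(disease_preset = "observational", onset = "cfhr1",
                       n_cases_bio = 382, n_controls_bio = 201,
                       n_advanced_bio = 242)
  b <- assemble_cohorts(cfg, seed = 71)
  # post-onset measurements of affected individuals are excluded from the
  # likelihood so the causal estimate rests on the genotype channel
  model <- build_iv_model(b, iv_model_spec(use_case_biomarkers = FALSE),
                          cohorts = c("population", "casecontrol_bio",
                                      "casecontrol_geno"))
  fit <- run_mcmc(model, n_chains = 2, n_iter = 600, n_warmup = 500, seed = 72)
  ps <- suppressWarnings(summarize_posterior(fit))
  rep <- observational_vs_causal_report(b, ps)
  expect_equal(nrow(rep), 2)
  row <- rep[rep$biomarker == "cfhr1", ]
  # measured CFHR1 looks protective observationally, yet the causal interval
  # covers the null (the generator's causal effect is zero)
  expect_lt(row$obs_or, 1)
  expect_true(row$causal_low <= 1 && row$causal_high >= 1)
})
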