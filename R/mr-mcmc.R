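# Internal flattened representation of an iv_model used by the sampler.
flatten_iv_model <- function(model) {
  rows <- model$rows
  spec <- model$spec
  L <- length(model$loci)
  nz <- length(spec$covariates)

  G <- do.call(rbind, lapply(rows, function(r) r$G))
  Z <- do.call(rbind, lapply(rows, function(r) r$Z))
  Zs <- sweep(sweep(Z, 2, model$z_center), 2, model$z_scale, "/")
  n <- nrow(G)
  cohort <- rep(names(rows), vapply(rows, function(r) nrow(r$G), 0))

  x_meas <- unlist(lapply(rows, function(r) r$x_meas), use.names = FALSE)
  x_expo <- unlist(lapply(rows, function(r) r$x_expo), use.names = FALSE)
  X_std <- matrix(NA_real_, n, 2)
  off <- 0
  for (r in rows) {
    ni <- nrow(r$G)
    if (!is.null(r$X)) {
      xs <- sweep(sweep(as.matrix(r$X), 2, model$x_center), 2,
                  model$x_scale, "/")
      X_std[off + seq_len(ni), ] <- xs
    }
    off <- off + ni
  }
  X_std[!x_meas, ] <- NA_real_

  D <- rep(NA_real_, n)
  off <- 0
  for (r in rows) {
    ni <- nrow(r$G)
    if (!is.null(r$D)) D[off + seq_len(ni)] <- r$D
    off <- off + ni
  }

  mcoh <- names(rows)[vapply(rows, function(r) any(r$x_expo), TRUE)]
  ocoh <- names(rows)[vapply(rows, function(r) !is.null(r$D), TRUE)]
  # exposure design: common intercept, offsets for non-reference measured
  # cohorts, all loci, standardized covariates
  w_names <- c("intercept",
               if (length(mcoh) > 1) paste0("offset_", mcoh[-1]),
               model$loci, colnames(Z))
  p_w <- length(w_names)

  out_idx <- which(!is.na(D))
  lat_idx <- which(!x_meas)
  meas_idx <- which(x_meas)
  expo_idx <- which(x_expo)
  psi_names <- c(paste0("gamma_", ocoh),
                 paste0("theta_", spec$exposures),
                 if (length(spec$pleiotropy)) paste0("delta_", spec$pleiotropy),
                 paste0("phi_", colnames(Z)))

  list(n = n, G = G, Zs = Zs, D = D, cohort = cohort,
       x_meas = x_meas, X_std = X_std,
       mcoh = mcoh, ocoh = ocoh, w_names = w_names, p_w = p_w,
       out_idx = out_idx, lat_idx = lat_idx, meas_idx = meas_idx,
       expo_idx = expo_idx,
       psi_names = psi_names, L = L, nz = nz)
}

log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18
  out[big] <- x[big] + exp(-x[big])
  out
}

bernoulli_ll <- function(d, eta) sum(d * eta - log1pexp(eta))

#' Run the Metropolis-within-Gibbs sampler for the instrumental-variable model
#'
#' The exposure-model coefficient matrix is drawn by a conjugate
#' matrix-normal Gibbs step; the residual covariance (two SDs and a
#' correlation), the outcome coefficients and the gaussian outcome SD (if
#' applicable) are updated by adaptive random-walk Metropolis; latent
#' exposures of outcome-only individuals are updated by a vectorized
#' per-individual Metropolis step; missing genotypes are drawn from their
#' categorical full conditionals. Step sizes adapt toward standard
#' acceptance targets during warmup only.
#'
#' @param model an [build_iv_model()] object.
#' @param n_chains number of chains (at least 2 for diagnostics).
#' @param n_iter post-warmup draws per chain.
#' @param n_warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @return object of class `iv_draws`: `draws` is an `n_iter x n_chains x
#'   n_parameters` array, plus parameter names, acceptance diagnostics and
#'   the model.
#' @export
run_mcmc <- function(model, n_chains = 4, n_iter = 2000, n_warmup = 1000,
                     seed = 1) {
  stopifnot(inherits(model, "iv_model"), n_chains >= 2)
  fl <- flatten_iv_model(model)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- run_one_chain(model, fl, n_iter, n_warmup,
                                  seed = seed + ch, jitter = 0.05)
  }
  par_names <- colnames(chains[[1]]$draws)
  draws <- array(NA_real_, dim = c(n_iter, n_chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(n_chains)) draws[, ch, ] <- chains[[ch]]$draws
  structure(list(draws = draws, par_names = par_names,
                 accept = lapply(chains, `[[`, "accept"),
                 model = model, seed = seed,
                 n_iter = n_iter, n_warmup = n_warmup),
            class = "iv_draws")
}

run_one_chain <- function(model, fl, n_iter, n_warmup, seed, jitter = 0.05) {
  spec <- model$spec
  tau2 <- spec$prior_sd_coef^2
  s_sigma <- spec$prior_sd_sigma
  gaussian_out <- model$outcome_family == "gaussian"
  with_seed(seed, {
    n <- fl$n; L <- fl$L; nz <- fl$nz
    ## initial missing-genotype imputation
    G <- fl$G
    miss <- which(is.na(G), arr.ind = TRUE)
    if (nrow(miss)) {
      for (k in seq_len(nrow(miss))) {
        pr <- model$hwe_prior[, miss[k, 2]]
        G[miss[k, 1], miss[k, 2]] <- sample(0:2, 1, prob = pr)
      }
    }
    build_W <- function(G) {
      W <- matrix(0, n, fl$p_w, dimnames = list(NULL, fl$w_names))
      W[, "intercept"] <- 1
      if (length(fl$mcoh) > 1) {
        for (m in fl$mcoh[-1]) W[fl$cohort == m, paste0("offset_", m)] <- 1
      }
      W[, model$loci] <- G
      W[, colnames(fl$Zs)] <- fl$Zs
      W
    }
    W <- build_W(G)

    meas <- fl$meas_idx; lat <- fl$lat_idx; out_idx <- fl$out_idx
    expo <- fl$expo_idx
    n_lat <- length(lat)
    D_out <- fl$D[out_idx]

    ## initial exposure fit on exposure-model rows
    Wm <- W[expo, , drop = FALSE]
    Xm <- fl$X_std[expo, , drop = FALSE]
    Rm <- crossprod(Wm) + diag(1e-6, fl$p_w)
    B <- solve(Rm, crossprod(Wm, Xm))
    B <- B + matrix(stats::rnorm(length(B), 0, jitter), nrow(B))
    res_m <- Xm - Wm %*% B
    Sig <- stats::cov(res_m)
    Sig[1, 2] <- Sig[2, 1] <- 0.9 * Sig[1, 2]
    sig1 <- sqrt(Sig[1, 1]); sig2 <- sqrt(Sig[2, 2])
    rho <- Sig[1, 2] / (sig1 * sig2)

    ## latent exposures start at their prior means plus noise
    Xl <- if (n_lat) {
      (W[lat, , drop = FALSE] %*% B) +
        matrix(stats::rnorm(2 * n_lat, 0, 0.2), n_lat, 2)
    } else matrix(0, 0, 2)

    ## outcome coefficient vector psi and design
    n_psi <- length(fl$psi_names)
    psi <- stats::rnorm(n_psi, 0, jitter)
    names(psi) <- fl$psi_names
    for (oc in fl$ocoh) {
      dbar <- mean(fl$D[fl$cohort == oc], na.rm = TRUE)
      psi[paste0("gamma_", oc)] <- stats::qlogis(min(max(dbar, 0.02), 0.98)) +
        stats::rnorm(1, 0, jitter)
    }
    ## warm-start theta/delta/phi from a quick fit on rows with measured
    ## exposures and outcome
    mo <- intersect(meas, out_idx)
    if (length(mo) > 50 && !gaussian_out) {
      df0 <- data.frame(d = fl$D[mo], fl$X_std[mo, , drop = FALSE],
                        G[mo, spec$pleiotropy, drop = FALSE],
                        fl$Zs[mo, , drop = FALSE])
      fit0 <- try(suppressWarnings(
        stats::glm(d ~ ., family = stats::binomial(), data = df0)),
        silent = TRUE)
    if (!inherits(fit0, "try-error") && fit0$converged) {
        cf <- stats::coef(fit0)[-1]
        tgt <- c(paste0("theta_", spec$exposures),
                 if (length(spec$pleiotropy)) paste0("delta_", spec$pleiotropy),
                 paste0("phi_", colnames(fl$Zs)))
        ok <- is.finite(cf)
        psi[tgt[ok]] <- cf[ok] + stats::rnorm(sum(ok), 0, jitter)
      }
    }
    sigma_y <- if (gaussian_out) stats::sd(D_out) else NA_real_

    ## outcome design matrix over out_idx rows
    pleio_center <- 2 * model$maf_hat[spec$pleiotropy]
    build_Mout <- function(G, Xl) {
      Xcur <- fl$X_std
      if (n_lat) Xcur[lat, ] <- Xl
      M <- cbind(
        vapply(fl$ocoh, function(oc) as.numeric(fl$cohort[out_idx] == oc),
               numeric(length(out_idx))),
        Xcur[out_idx, , drop = FALSE],
        if (length(spec$pleiotropy))
          sweep(G[out_idx, spec$pleiotropy, drop = FALSE], 2, pleio_center),
        fl$Zs[out_idx, , drop = FALSE])
      colnames(M) <- fl$psi_names
      M
    }
    Mout <- build_Mout(G, Xl)
    eta <- drop(Mout %*% psi)

    out_ll <- function(eta, sigma_y) {
      if (gaussian_out) {
        sum(stats::dnorm(D_out, eta, sigma_y, log = TRUE))
      } else bernoulli_ll(D_out, eta)
    }

    ## which latent rows carry an outcome (all, in practice)
    lat_out <- match(lat, out_idx)        # NA if latent row has no outcome
    lat_has_out <- !is.na(lat_out)

    ## step sizes
    step_psi <- rep(0.1, n_psi)
    step_sig <- 0.1
    step_lat <- 0.5
    step_sy <- 0.1
    acc_psi <- numeric(n_psi); acc_sig <- 0; acc_lat <- 0; n_acc <- 0

    Sigma_inv <- function(s1, s2, r) {
      det <- (1 - r^2) * s1^2 * s2^2
      matrix(c(s2^2, -r * s1 * s2, -r * s1 * s2, s1^2), 2) / det
    }

    total_iter <- n_warmup + n_iter
    keep <- matrix(NA_real_, n_iter,
                   2 * fl$p_w + 3 + n_psi + as.integer(gaussian_out))
    colnames(keep) <- c(paste0("b_", spec$exposures[1], "_", fl$w_names),
                        paste0("b_", spec$exposures[2], "_", fl$w_names),
                        paste0("sigma_", spec$exposures), "rho",
                        fl$psi_names, if (gaussian_out) "sigma_y")

    exp_rows <- c(expo, lat)
    W_exp <- W[exp_rows, , drop = FALSE]
    WtW <- crossprod(W_exp)

    for (it in seq_len(total_iter)) {
      warm <- it <= n_warmup
      adapt_rate <- if (warm) min(0.2, 5 / sqrt(it)) else 0

      ## --- Gibbs: exposure coefficient matrix (matrix-normal) ---
      Xfull <- rbind(fl$X_std[expo, , drop = FALSE], Xl)
      Sig <- matrix(c(sig1^2, rho * sig1 * sig2,
                      rho * sig1 * sig2, sig2^2), 2)
      R <- WtW + diag(1 / tau2, fl$p_w)
      Ru <- chol(R)
      M_post <- backsolve(Ru, backsolve(Ru, crossprod(W_exp, Xfull),
                                        transpose = TRUE))
      E <- matrix(stats::rnorm(2 * fl$p_w), fl$p_w, 2)
      B <- M_post + backsolve(Ru, E) %*% chol(Sig)
      rownames(B) <- fl$w_names

      resid <- Xfull - W_exp %*% B
      S <- crossprod(resid)
      n_exp <- nrow(resid)

      ## --- MH: residual covariance (log s1, log s2, atanh rho) ---
      sig_lp <- function(s1, s2, r) {
        ld <- -n_exp * (log(s1) + log(s2)) - 0.5 * n_exp * log(1 - r^2)
        Si <- Sigma_inv(s1, s2, r)
        ld - 0.5 * sum(Si * S) - s1^2 / (2 * s_sigma^2) -
          s2^2 / (2 * s_sigma^2) +
          log(s1) + log(s2) + log(1 - r^2)   # Jacobians + half-normal priors
      }
      cur <- c(log(sig1), log(sig2), atanh(rho))
      prop <- cur + stats::rnorm(3, 0, step_sig)
      lp_cur <- sig_lp(sig1, sig2, rho)
      lp_prop <- sig_lp(exp(prop[1]), exp(prop[2]), tanh(prop[3]))
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        sig1 <- exp(prop[1]); sig2 <- exp(prop[2]); rho <- tanh(prop[3])
        acc_sig <- acc_sig + 1
      }
      if (warm) {
        a <- min(1, exp(lp_prop - lp_cur))
        if (!is.finite(a)) a <- 0
        step_sig <- exp(log(step_sig) + adapt_rate * (a - 0.3))
      }
      Sinv <- Sigma_inv(sig1, sig2, rho)

      ## --- MH: outcome coefficients, componentwise ---
      ll_cur <- out_ll(eta, sigma_y)
      for (k in seq_len(n_psi)) {
        dpsi <- stats::rnorm(1, 0, step_psi[k])
        eta_p <- eta + dpsi * Mout[, k]
        ll_p <- out_ll(eta_p, sigma_y)
        lr <- ll_p - ll_cur +
          (psi[k]^2 - (psi[k] + dpsi)^2) / (2 * tau2)
        a <- min(1, exp(lr))
        if (!is.finite(a)) a <- 0
        if (stats::runif(1) < a) {
          psi[k] <- psi[k] + dpsi; eta <- eta_p; ll_cur <- ll_p
          acc_psi[k] <- acc_psi[k] + 1
        }
        if (warm) step_psi[k] <- exp(log(step_psi[k]) + adapt_rate * (a - 0.44))
      }

      if (gaussian_out) {
        prop_sy <- sigma_y * exp(stats::rnorm(1, 0, step_sy))
        lr <- out_ll(eta, prop_sy) - out_ll(eta, sigma_y) +
          (sigma_y^2 - prop_sy^2) / (2 * (3 * stats::sd(D_out))^2) +
          log(prop_sy) - log(sigma_y)
        if (is.finite(lr) && log(stats::runif(1)) < lr) sigma_y <- prop_sy
      }

      ## --- MH: latent exposures (vectorized over individuals) ---
      if (n_lat) {
        Ml <- W[lat, , drop = FALSE] %*% B
        e_cur <- Xl - Ml
        prop <- Xl + matrix(stats::rnorm(2 * n_lat, 0, step_lat), n_lat)
        e_prop <- prop - Ml
        q_cur <- Sinv[1, 1] * e_cur[, 1]^2 + Sinv[2, 2] * e_cur[, 2]^2 +
          2 * Sinv[1, 2] * e_cur[, 1] * e_cur[, 2]
        q_prop <- Sinv[1, 1] * e_prop[, 1]^2 + Sinv[2, 2] * e_prop[, 2]^2 +
          2 * Sinv[1, 2] * e_prop[, 1] * e_prop[, 2]
        lr <- -0.5 * (q_prop - q_cur)
        th <- psi[paste0("theta_", spec$exposures)]
        io <- lat_out[lat_has_out]
        eta_l <- eta[io]
        eta_lp <- eta_l + th[1] * (prop[lat_has_out, 1] - Xl[lat_has_out, 1]) +
          th[2] * (prop[lat_has_out, 2] - Xl[lat_has_out, 2])
        d_l <- D_out[io]
        if (gaussian_out) {
          dll <- stats::dnorm(d_l, eta_lp, sigma_y, log = TRUE) -
            stats::dnorm(d_l, eta_l, sigma_y, log = TRUE)
        } else {
          dll <- d_l * (eta_lp - eta_l) - log1pexp(eta_lp) + log1pexp(eta_l)
        }
        lr[lat_has_out] <- lr[lat_has_out] + dll
        acc <- log(stats::runif(n_lat)) < lr
        if (any(acc)) {
          Xl[acc, ] <- prop[acc, ]
          changed <- which(lat_has_out & acc)
          if (length(changed)) {
            io_c <- lat_out[changed]
            eta[io_c] <- eta[io_c] +
              th[1] * (Xl[changed, 1] - Mout[io_c, names(th)[1]]) +
              th[2] * (Xl[changed, 2] - Mout[io_c, names(th)[2]])
            Mout[io_c, names(th)[1]] <- Xl[changed, 1]
            Mout[io_c, names(th)[2]] <- Xl[changed, 2]
          }
        }
        rate <- mean(acc)
        acc_lat <- acc_lat + rate
        if (warm) step_lat <- exp(log(step_lat) + adapt_rate * (rate - 0.35))
      }

      ## --- Gibbs: missing genotypes ---
      if (nrow(miss) && it %% 2 == 0) {
        G <- update_missing_genotypes(G, miss, model, fl, B, Sinv, psi,
                                      Xl, lat, expo, W)
        W <- build_W(G)
        W_exp <- W[exp_rows, , drop = FALSE]
        WtW <- crossprod(W_exp)
        Mout <- build_Mout(G, Xl)
        eta <- drop(Mout %*% psi)
      }

      n_acc <- n_acc + 1
      if (!warm) {
        keep[it - n_warmup, ] <- c(B[, 1], B[, 2], sig1, sig2, rho, psi,
                                   if (gaussian_out) sigma_y)
      }
    }
    list(draws = keep,
         accept = list(psi = acc_psi / total_iter,
                       sigma = acc_sig / total_iter,
                       latent = if (n_lat) acc_lat / total_iter else NA))
  })
}

# categorical full-conditional update of missing genotype entries, locus by
# locus; instrument-pair entries use the EM haplotype joint as prior given
# the partner genotype, other loci use marginal HWE priors
update_missing_genotypes <- function(G, miss, model, fl, B, Sinv, psi,
                                     Xl, lat, expo, W) {
  spec <- model$spec
  Xcur <- fl$X_std
  if (length(lat)) Xcur[lat, ] <- Xl
  has_x <- seq_len(fl$n) %in% c(expo, lat)
  inst <- spec$instruments
  for (l in unique(miss[, 2])) {
    rows_l <- miss[miss[, 2] == l, 1]
    lname <- model$loci[l]
    b_l <- B[lname, ]                      # effect of this locus on X pair
    d_l <- if (lname %in% spec$pleiotropy) {
      psi[paste0("delta_", lname)]
    } else 0
    logp <- matrix(0, length(rows_l), 3)
    ## prior
    if (length(inst) >= 2 && lname %in% inst && !is.null(model$pair_joint)) {
      partner <- setdiff(inst, lname)[1]
      gp <- G[rows_l, partner]
      joint <- if (lname == inst[1]) model$pair_joint else t(model$pair_joint)
      gp_safe <- ifelse(is.na(gp), 0L, gp)
      pr <- joint[, gp_safe + 1, drop = FALSE]     # 3 x n, P(g_l = ., g_p)
      if (any(is.na(gp))) {
        pr[, is.na(gp)] <- model$hwe_prior[, l]
      }
      pr <- sweep(pr, 2, colSums(pr), "/")
      logp <- logp + t(log(pmax(pr, 1e-12)))
    } else {
      logp <- logp + matrix(rep(log(pmax(model$hwe_prior[, l], 1e-12)),
                                each = length(rows_l)), ncol = 3)
    }
    ## exposure likelihood
    hx <- has_x[rows_l]
    if (any(hx)) {
      r_hx <- rows_l[hx]
      base <- Xcur[r_hx, , drop = FALSE] -
        (W[r_hx, , drop = FALSE] %*% B -
           outer(G[r_hx, l], b_l))   # residual with g_l = 0
      for (g in 0:2) {
        e1 <- base[, 1] - g * b_l[1]; e2 <- base[, 2] - g * b_l[2]
        q <- Sinv[1, 1] * e1^2 + Sinv[2, 2] * e2^2 + 2 * Sinv[1, 2] * e1 * e2
        logp[hx, g + 1] <- logp[hx, g + 1] - 0.5 * q
      }
    }
    ## outcome likelihood (direct effect only)
    if (d_l != 0) {
      io <- match(rows_l, fl$out_idx)
      ho <- !is.na(io)
      if (any(ho)) {
        d_obs <- fl$D[rows_l[ho]]
        # eta with g_l = 0 requires removing current contribution; compute
        # from scratch cheaply for these rows
        for (g in 0:2) {
          Gtmp <- G[rows_l[ho], , drop = FALSE]
          Gtmp[, l] <- g
          eta_g <- outcome_eta_rows(rows_l[ho], Gtmp, Xcur, fl, psi, model)
          logp[ho, g + 1] <- logp[ho, g + 1] +
            d_obs * eta_g - log1pexp(eta_g)
        }
      }
    }
    ## sample
    mx <- apply(logp, 1, max)
    p <- exp(logp - mx)
    p <- p / rowSums(p)
    u <- stats::runif(length(rows_l))
    newg <- ifelse(u < p[, 1], 0L, ifelse(u < p[, 1] + p[, 2], 1L, 2L))
    G[cbind(rows_l, l)] <- newg
  }
  G
}

outcome_eta_rows <- function(rows, Grows, Xcur, fl, psi, model) {
  spec <- model$spec
  eta <- numeric(length(rows))
  for (oc in fl$ocoh) {
    eta <- eta + psi[paste0("gamma_", oc)] * (fl$cohort[rows] == oc)
  }
  th <- psi[paste0("theta_", spec$exposures)]
  eta <- eta + th[1] * Xcur[rows, 1] + th[2] * Xcur[rows, 2]
  if (length(spec$pleiotropy)) {
    ctr <- 2 * model$maf_hat[spec$pleiotropy]
    for (j in seq_along(spec$pleiotropy)) {
      eta <- eta + psi[paste0("delta_", spec$pleiotropy[j])] *
        (Grows[, spec$pleiotropy[j]] - ctr[j])
    }
  }
  for (z in colnames(fl$Zs)) {
    eta <- eta + psi[paste0("phi_", z)] * fl$Zs[rows, z]
  }
  eta
}
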