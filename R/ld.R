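#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased dosage data. Only double heterozygotes are phase-ambiguous; the
#' EM algorithm splits them between the coupling (AB/ab) and repulsion
#' (Ab/aB) configurations in proportion to the current haplotype
#' frequencies. The log-likelihood is non-decreasing across iterations
#' (asserted) and iteration stops when it improves by less than `tol`.
#' Initialization is at linkage equilibrium.
#'
#' @param dosage_a,dosage_b dosage vectors (0/1/2); missing values are
#'   dropped pairwise.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return list of class `ld_result`: `freqs` (named `ab`, `aB`, `Ab`, `AB`
#'   haplotype frequencies, capital = minor allele), `D`, `d_prime`, `r2`,
#'   `maf_a`, `maf_b`, `n`, `n_em_iters`, `loglik`, `loglik_trace`.
#' @export
em_haplotype_freqs <- function(dosage_a, dosage_b, tol = 1e-10,
                               max_iter = 1000) {
  keep <- is.finite(dosage_a) & is.finite(dosage_b)
  a <- dosage_a[keep]; b <- dosage_b[keep]
  n <- length(a)
  if (n < 10) stop("need at least 10 paired non-missing genotypes")
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("monomorphic locus")
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(a == i & b == j)

  p_a <- mean(a) / 2; p_b <- mean(b) / 2
  # haplotype order: (a_allele, b_allele) with 1 = minor
  f <- c(`00` = (1 - p_a) * (1 - p_b), `01` = (1 - p_a) * p_b,
         `10` = p_a * (1 - p_b), `11` = p_a * p_b)

  # expected haplotype counts contributed by each unambiguous genotype cell
  # cell (i, j) = dosages; haplotype pair determined unless i == 1 && j == 1
  hap_count <- function(f) {
    cnt <- c(`00` = 0, `01` = 0, `10` = 0, `11` = 0)
    for (i in 0:2) for (j in 0:2) {
      nij <- tab[i + 1, j + 1]
      if (nij == 0) next
      if (i == 1 && j == 1) {
        pc <- f["11"] * f["00"]          # coupling AB/ab
        pr <- f["10"] * f["01"]          # repulsion Ab/aB
        wc <- if (pc + pr > 0) pc / (pc + pr) else 0.5
        cnt["11"] <- cnt["11"] + nij * wc
        cnt["00"] <- cnt["00"] + nij * wc
        cnt["10"] <- cnt["10"] + nij * (1 - wc)
        cnt["01"] <- cnt["01"] + nij * (1 - wc)
      } else {
        h1 <- c(if (i >= 1) 1 else 0, if (j >= 1) 1 else 0)
        h2 <- c(if (i == 2) 1 else 0, if (j == 2) 1 else 0)
        # distribute the two minor-a alleles/minor-b alleles: for i or j == 1
        # the single minor allele goes on the first haplotype
        k1 <- paste0(h1[1], h1[2]); k2 <- paste0(h2[1], h2[2])
        cnt[k1] <- cnt[k1] + nij
        cnt[k2] <- cnt[k2] + nij
      }
    }
    cnt
  }
  loglik <- function(f) {
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      nij <- tab[i + 1, j + 1]
      if (nij == 0) next
      pg <- genotype_prob(f, i, j)
      ll <- ll + nij * log(pg)
    }
    ll
  }
  trace <- numeric()
  ll_old <- -Inf
  iters <- 0
  repeat {
    iters <- iters + 1L
    cnt <- hap_count(f)
    f_new <- cnt / sum(cnt)
    ll <- loglik(f_new)
    if (ll < ll_old - 1e-8) stop("EM log-likelihood decreased (internal error)")
    trace <- c(trace, ll)
    f <- f_new
    if (ll - ll_old < tol || iters >= max_iter) break
    ll_old <- ll
  }
  p_a <- f[["10"]] + f[["11"]]
  p_b <- f[["01"]] + f[["11"]]
  D <- f[["11"]] - p_a * p_b
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  structure(list(
    freqs = c(ab = f[["00"]], aB = f[["01"]], Ab = f[["10"]], AB = f[["11"]]),
    D = D, d_prime = if (d_max > 0) abs(D) / d_max else NA_real_,
    r2 = r2, maf_a = p_a, maf_b = p_b, n = n,
    n_em_iters = iters, loglik = trace[length(trace)],
    loglik_trace = trace), class = "ld_result")
}

# P(genotype pair) under HWE on haplotypes
genotype_prob <- function(f, i, j) {
  # sum over unordered haplotype pairs consistent with dosages (i, j)
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  key <- c("00", "01", "10", "11")
  p <- 0
  for (u in 1:4) for (v in 1:4) {
    if (haps[u, 1] + haps[v, 1] == i && haps[u, 2] + haps[v, 2] == j) {
      p <- p + f[[key[u]]] * f[[key[v]]]
    }
  }
  p
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("Two-locus LD (n = %d): r2 = %.4f, D' = %.4f, D = %.5f (%d EM iterations)\n",
              x$n, x$r2, x$d_prime, x$D, x$n_em_iters))
  invisible(x)
}

#' Pearson correlation of a dosage with a quantitative value
#'
#' Plain Pearson correlation with a two-sided t-test p-value (n - 2 df), as
#' used for genotype/biomarker scatter summaries.
#'
#' @param dosage_a dosage (or any numeric) vector.
#' @param values_b numeric vector.
#' @return list with `r`, `p`, `n`.
#' @export
dosage_correlation <- function(dosage_a, values_b) {
  keep <- is.finite(dosage_a) & is.finite(values_b)
  a <- dosage_a[keep]; b <- values_b[keep]
  if (length(a) < 3) stop("need at least 3 paired observations")
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("zero variance input")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
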