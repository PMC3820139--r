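#' Locus definition table
#'
#' Builds and validates a table of biallelic loci. A "deletion" locus is a
#' structural allele (such as the common ~86 kb CFHR3/CFHR1 deletion) treated
#' as a biallelic variant on haplotypes, so its dosage is the count of
#' deletion-bearing haplotypes (0/1/2).
#'
#' @param name character vector of unique locus labels.
#' @param kind `"snp"` or `"deletion"` per locus.
#' @param maf minor (or deletion) allele frequency per locus, in (0, 0.5].
#' @param role role tag per locus: `"index_regulatory"`, `"pleiotropic"` or
#'   `"neutral"`.
#' @return A `data.frame` with class `locus_table`.
#' @export
locus_table <- function(name, kind, maf, role) {
  stopifnot(length(name) == length(kind), length(name) == length(maf),
            length(name) == length(role))
  if (anyDuplicated(name)) stop("locus names must be unique")
  if (!all(kind %in% c("snp", "deletion"))) stop("kind must be 'snp' or 'deletion'")
  if (!all(role %in% c("index_regulatory", "pleiotropic", "neutral"))) {
    stop("unknown role tag")
  }
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  out <- data.frame(name = name, kind = kind, maf = maf, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Maximum attainable two-locus r-squared given allele frequencies
#'
#' For minor-allele frequencies `p_a`, `p_b` and positive coupling the
#' disequilibrium coefficient D is bounded by
#' `min(p_a * (1 - p_b), (1 - p_a) * p_b)` (negative coupling by
#' `min(p_a * p_b, (1 - p_a) * (1 - p_b))`); the squared correlation is
#' `D^2 / (p_a (1-p_a) p_b (1-p_b))`.
#'
#' @param p_a,p_b minor allele frequencies.
#' @param sign `+1` for coupling of the two minor alleles, `-1` for repulsion.
#' @return Largest feasible r-squared.
#' @export
max_r2 <- function(p_a, p_b, sign = 1) {
  q_a <- 1 - p_a; q_b <- 1 - p_b
  d_max <- if (sign >= 0) min(p_a * q_b, q_a * p_b) else min(p_a * p_b, q_a * q_b)
  d_max^2 / (p_a * q_a * p_b * q_b)
}

#' Build a haplotype model with target pairwise LD to an index locus
#'
#' Constructs a multi-locus haplotype distribution in which every non-index
#' locus is conditionally independent of the others given the index-locus
#' allele (a chain factorization through the index locus). Each requested
#' pairwise r-squared with the index locus is realized exactly: the coupling
#' coefficient is `D = r * sqrt(p_a q_a p_b q_b)` with `r = sign * sqrt(r2)`,
#' and conditional minor-allele probabilities at locus b given the index
#' allele follow from the 2x2 haplotype table.
#'
#' @param loci a [locus_table()] containing exactly one `index_regulatory`
#'   locus.
#' @param targets `data.frame` with columns `locus` (a non-index locus name),
#'   `r2` (target squared correlation with the index locus in `[0, 1]`) and
#'   optionally `sign` (+1/-1, default +1). Loci without a target are
#'   simulated in linkage equilibrium with the index locus.
#' @return An object of class `haplotype_model`.
#' @export
build_haplotype_model <- function(loci, targets = NULL) {
  stopifnot(inherits(loci, "data.frame"))
  idx <- which(loci$role == "index_regulatory")
  if (length(idx) != 1L) stop("exactly one index_regulatory locus is required")
  if (any(loci$maf <= 0 | loci$maf > 0.5)) stop("maf must lie in (0, 0.5]")
  p_a <- loci$maf[idx]
  q_a <- 1 - p_a

  r2 <- setNames(rep(0, nrow(loci)), loci$name)
  sgn <- setNames(rep(1, nrow(loci)), loci$name)
  if (!is.null(targets) && nrow(targets)) {
    if (!all(targets$locus %in% loci$name)) stop("LD target names unknown")
    if (loci$name[idx] %in% targets$locus) {
      stop("LD targets must reference non-index loci against the index locus")
    }
    if (any(targets$r2 < 0 | targets$r2 > 1)) stop("r2 targets must lie in [0, 1]")
    r2[targets$locus] <- targets$r2
    if (!is.null(targets$sign)) sgn[targets$locus] <- sign(targets$sign)
  }

  # conditional P(minor at locus b | index allele) for each locus
  cond1 <- cond0 <- d_vec <- numeric(nrow(loci))
  for (j in seq_len(nrow(loci))) {
    p_b <- loci$maf[j]
    q_b <- 1 - p_b
    if (j == idx) {
      cond1[j] <- 1; cond0[j] <- 0; d_vec[j] <- p_a * q_a
      next
    }
    r <- sgn[j] * sqrt(r2[j])
    d <- r * sqrt(p_a * q_a * p_b * q_b)
    d_bound <- if (d >= 0) min(p_a * q_b, q_a * p_b) else min(p_a * p_b, q_a * q_b)
    if (abs(d) > d_bound + 1e-12) {
      stop(sprintf(
        "infeasible LD target for locus '%s': requested r2 = %.4g but the maximum attainable r2 for MAFs (%.4g, %.4g) is %.4g",
        loci$name[j], r2[j], p_a, p_b, max_r2(p_a, p_b, sign = r)))
    }
    d_vec[j] <- d
    cond1[j] <- (p_b * p_a + d) / p_a   # P(b minor | index minor)
    cond0[j] <- (p_b * q_a - d) / q_a   # P(b minor | index major)
  }
  if (any(cond1 < -1e-12 | cond1 > 1 + 1e-12 | cond0 < -1e-12 | cond0 > 1 + 1e-12)) {
    stop("internal error: conditional haplotype probabilities outside [0, 1]")
  }
  cond1 <- pmin(pmax(cond1, 0), 1)
  cond0 <- pmin(pmax(cond0, 0), 1)

  model <- structure(list(
    loci = loci,
    index = loci$name[idx],
    p_index = p_a,
    cond1 = setNames(cond1, loci$name),
    cond0 = setNames(cond0, loci$name),
    D = setNames(d_vec, loci$name),
    r2_target = r2
  ), class = "haplotype_model")

  chk <- implied_ld(model)
  if (max(abs(chk$maf - loci$maf)) > 1e-9) {
    stop("internal error: implied MAFs deviate from specification")
  }
  off <- abs(chk$r2 - r2)[loci$name != model$index]
  if (length(off) && max(off) > 1e-9) {
    stop("internal error: implied r2 deviates from LD targets")
  }
  model
}

#' Implied marginal MAFs and index-pairwise LD of a haplotype model
#'
#' @param model a `haplotype_model`.
#' @return list with `maf`, `r2`, `d_prime` vectors (index locus entries are
#'   its own MAF and degenerate r2/D' of 1).
#' @export
implied_ld <- function(model) {
  p_a <- model$p_index
  q_a <- 1 - p_a
  maf <- p_a * model$cond1 + q_a * model$cond0
  d <- p_a * model$cond1 - p_a * maf   # E[h_a h_b] - p_a p_b
  denom <- p_a * q_a * maf * (1 - maf)
  r2 <- ifelse(denom > 0, d^2 / denom, NA_real_)
  d_max <- ifelse(d >= 0, pmin(p_a * (1 - maf), q_a * maf),
                  pmin(p_a * maf, q_a * (1 - maf)))
  d_prime <- ifelse(d_max > 0, abs(d) / d_max, NA_real_)
  i <- model$loci$name == model$index
  r2[i] <- 1; d_prime[i] <- 1
  list(maf = unname(maf), r2 = unname(r2), d_prime = unname(d_prime))
}

#' Four-haplotype frequency table for the index locus and one other locus
#'
#' @param model a `haplotype_model`.
#' @param locus non-index locus name.
#' @return named numeric vector `c(ab, aB, Ab, AB)` where lower case denotes
#'   the major allele and the first position is the index locus.
#' @export
pair_haplotype_freqs <- function(model, locus) {
  stopifnot(locus %in% model$loci$name, locus != model$index)
  p_a <- model$p_index
  c1 <- model$cond1[[locus]]; c0 <- model$cond0[[locus]]
  c(ab = (1 - p_a) * (1 - c0), aB = (1 - p_a) * c0,
    Ab = p_a * (1 - c1), AB = p_a * c1)
}

#' Analytic covariance matrix of locus dosages under a haplotype model
#'
#' Under the chain factorization, the haplotype-level covariance between two
#' non-index loci b and c is `D_b * D_c / (p_a * q_a)`; dosage covariances are
#' twice the haplotype covariances (two independent haplotypes per
#' individual under Hardy-Weinberg equilibrium).
#'
#' @param model a `haplotype_model`.
#' @return L x L dosage covariance matrix.
#' @export
dosage_covariance <- function(model) {
  nm <- model$loci$name
  p <- model$loci$maf
  p_a <- model$p_index; q_a <- 1 - p_a
  d <- model$D
  L <- length(nm)
  hap_cov <- outer(d, d) / (p_a * q_a)
  diag(hap_cov) <- p * (1 - p)
  i <- which(nm == model$index)
  hap_cov[i, ] <- d
  hap_cov[, i] <- d
  hap_cov[i, i] <- p_a * q_a
  out <- 2 * hap_cov
  dimnames(out) <- list(nm, nm)
  out
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("Haplotype model:", nrow(x$loci), "loci, index locus", x$index,
      sprintf("(MAF %.3f)\n", x$p_index))
  ld <- implied_ld(x)
  tab <- data.frame(locus = x$loci$name, kind = x$loci$kind,
                    maf = round(ld$maf, 4), r2_index = round(ld$r2, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
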