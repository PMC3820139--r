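#' Simulate a population pedigree of nuclear families plus unrelated singletons
#'
#' Each family consists of two unrelated founder parents and `sibship_size`
#' full siblings. Parents can be excluded from the phenotyped cohort (the
#' usual design for sibship-based heritability cohorts) while still being used
#' for gene dropping.
#'
#' @param n_families number of nuclear families.
#' @param sibship_size number of full siblings per family.
#' @param n_unrelated number of additional unrelated singletons.
#' @param phenotype_parents logical; if `FALSE` parents are flagged
#'   `phenotyped = FALSE` and excluded from the cohort kinship matrix returned
#'   by [kinship_matrix()] with `phenotyped_only = TRUE`.
#' @return An object of class `pedigree`: a `data.frame` with columns `id`,
#'   `father`, `mother` (0 for founders), `family` and `phenotyped`.
#' @export
simulate_pedigrees <- function(n_families = 0, sibship_size = 2,
                               n_unrelated = 0, phenotype_parents = TRUE) {
  stopifnot(n_families >= 0, n_unrelated >= 0, sibship_size >= 1)
  rows <- list()
  next_id <- 1L
  for (f in seq_len(n_families)) {
    fa <- next_id; mo <- next_id + 1L
    kids <- next_id + 1L + seq_len(sibship_size)
    rows[[f]] <- data.frame(
      id = c(fa, mo, kids),
      father = c(0L, 0L, rep(fa, sibship_size)),
      mother = c(0L, 0L, rep(mo, sibship_size)),
      family = f,
      phenotyped = c(phenotype_parents, phenotype_parents,
                     rep(TRUE, sibship_size)))
    next_id <- next_id + 2L + sibship_size
  }
  if (n_unrelated > 0) {
    ids <- next_id - 1L + seq_len(n_unrelated)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids, father = 0L, mother = 0L,
      family = n_families + seq_len(n_unrelated), phenotyped = TRUE)
  }
  ped <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), father = integer(), mother = integer(),
               family = integer(), phenotyped = logical())
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Additive-relationship (2 * kinship) matrix of a pedigree
#'
#' Computes kinship coefficients by the standard tabular recursion over
#' individuals ordered so that parents precede offspring, then returns the
#' additive relationship matrix K = 2 * Phi (unit diagonal for non-inbred
#' individuals, 0.5 for parent-offspring and full-sib pairs).
#'
#' @param ped a `pedigree`.
#' @param phenotyped_only restrict the returned matrix to phenotyped rows.
#' @return symmetric PSD matrix with dimnames set to ids.
#' @export
kinship_matrix <- function(ped, phenotyped_only = FALSE) {
  n <- nrow(ped)
  phi <- matrix(0, n, n)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  for (k in seq_len(n)) {
    if (is.na(fa[k])) {                    # founder
      phi[k, k] <- 0.5
    } else {
      j <- seq_len(k - 1L)
      phi[k, j] <- phi[j, k] <- 0.5 * (phi[fa[k], j] + phi[mo[k], j])
      phi[k, k] <- 0.5 * (1 + phi[fa[k], mo[k]])
    }
  }
  K <- 2 * phi
  dimnames(K) <- list(ped$id, ped$id)
  if (phenotyped_only) K <- K[ped$phenotyped, ped$phenotyped, drop = FALSE]
  K
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      length(unique(x$family[x$father != 0])),
      "families with offspring,",
      sum(x$father == 0 & x$mother == 0), "founders\n")
  invisible(x)
}
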