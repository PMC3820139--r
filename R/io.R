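#' Write a dosage matrix as TSV
#'
#' Tab-separated matrix with a leading `sample_id` column and one column per
#' locus; missing dosages written as `NA`.
#'
#' @param dosages integer dosage matrix with rownames (sample ids).
#' @param path output path.
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(sample_id = rownames(dosages), dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dosage matrix from TSV
#' @param path file written by [write_dosage_tsv()].
#' @return integer matrix with sample ids as rownames.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' Write genotypes as a minimal VCF
#'
#' One record per locus on a synthetic contig (`chr1_sim`, consecutive
#' kilobase positions). SNPs are written with REF `A` / ALT `C`; deletion
#' loci use the symbolic ALT `<DEL>`. Genotypes are unphased (`0/1` style),
#' with the ALT allele counting the minor/deletion allele; missing dosages
#' become `./.`.
#'
#' @param dosages dosage matrix (individuals x loci, rownames = sample ids).
#' @param loci a [locus_table()] matching the columns.
#' @param path output path.
#' @export
write_vcf <- function(dosages, loci, path) {
  stopifnot(all(colnames(dosages) == loci$name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1_sim>",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(dosages))) {
    g <- dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1])
    alt <- if (loci$kind[j] == "deletion") "<DEL>" else "C"
    writeLines(paste(c("chr1_sim", j * 1000, loci$name[j], "A", alt, ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a minimal VCF or dosage TSV
#'
#' VCF parsing uses `vcfR` when installed and a plain-text fallback parser
#' otherwise; the ALT allele (including the symbolic `<DEL>`) is counted as
#' the dosage allele. Malformed records raise an error naming the line.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return dosage matrix with locus metadata in `attr(, "loci")` for VCF
#'   input.
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") return(read_dosage_tsv(path))
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c("./.", ".")) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
    fix <- vcfR::getFIX(v)
    out <- t(dos)
    colnames(out) <- fix[, "ID"]
    attr(out, "loci") <- data.frame(
      name = fix[, "ID"],
      kind = ifelse(fix[, "ALT"] == "<DEL>", "deletion", "snp"),
      stringsAsFactors = FALSE)
    return(out)
  }
  read_vcf_plain(path)
}

read_vcf_plain <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  if (length(cols) < 10) stop("malformed VCF header at line ", hdr)
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  dos <- matrix(NA_integer_, length(samples), length(body),
                dimnames = list(samples, NULL))
  ids <- character(length(body)); alts <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) != length(cols)) {
      stop("malformed VCF record at line ", hdr + i, " of ", path)
    }
    ids[i] <- f[3]; alts[i] <- f[5]
    gt <- f[-(1:9)]
    dos[, i] <- vapply(gt, function(x) {
      if (x %in% c("./.", ".")) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    }, 0L, USE.NAMES = FALSE)
  }
  colnames(dos) <- ids
  attr(dos, "loci") <- data.frame(
    name = ids, kind = ifelse(alts == "<DEL>", "deletion", "snp"),
    stringsAsFactors = FALSE)
  dos
}

#' Write / read a phenotype-covariate table as TSV
#' @param df data.frame (biomarkers, covariates, disease in any mix).
#' @param path file path.
#' @export
write_phenotypes_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a square kinship matrix as TSV with an id header row/column
#' @param K symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  if (nrow(K) != ncol(K)) stop("kinship matrix is not square")
  K
}

#' Write / read a qPCR plate export as TSV
#' @param plate `qpcr_plate` data.frame.
#' @param path file path.
#' @export
write_plate_tsv <- function(plate, path) {
  utils::write.table(as.data.frame(plate), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_plate_tsv
#' @param calibrator calibrator sample id to attach on read.
#' @param max_cycles sentinel cycle count to attach on read.
#' @export
read_plate_tsv <- function(path, calibrator = NULL, max_cycles = 40) {
  plate <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "well", "dye", "ct")
  if (!all(need %in% names(plate))) {
    stop("plate file must have columns: ", paste(need, collapse = ", "))
  }
  attr(plate, "calibrator") <- calibrator
  attr(plate, "max_cycles") <- max_cycles
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}

#' Load a pipeline/cohort configuration from YAML
#'
#' Unknown keys are rejected; known keys override the [cohort_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return a `cohort_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$biomarker_preset)) {
    raw$biomarker_preset <- unlist(raw$biomarker_preset)
  }
  do.call(cohort_config, raw)
}

#' Serialize / restore the generating truth record as JSON
#' @param truth `truth` element of a `cohort_bundle`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  # named atomic vectors must become JSON objects, not bare arrays
  namedify <- function(x) {
    if (is.list(x)) return(lapply(x, namedify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  jsonlite::write_json(namedify(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
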