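#' Simulate a triplicate qPCR plate for deletion copy-number genotyping
#'
#' Emulates a relative-quantification assay in which a target amplicon lies
#' inside the deleted segment (so its template copy number is 2 minus the
#' deletion dosage) and a reference amplicon (an autosomal two-copy control
#' such as HBB) normalizes input DNA. With perfect doubling per cycle, halving
#' the template delays the threshold cycle by exactly one cycle:
#' `Ct_target = base_ct - log2(copy / 2) / efficiency`. Zero-copy samples never
#' amplify and are reported at the no-amplification sentinel (`Ct = max_cycles`).
#'
#' @param copy_numbers integer vector in `{0, 1, 2}` of target-locus copies.
#' @param efficiency amplification efficiency factor (1 = perfect doubling).
#' @param base_ct expected Ct of a two-copy sample (both dyes).
#' @param ct_noise_sd per-well Ct noise SD in cycles.
#' @param max_cycles number of cycles run; also the sentinel Ct.
#' @param calibrator sample id (1-based index) used as the two-copy
#'   calibrator; defaults to the first two-copy sample.
#' @param seed integer seed.
#' @return `data.frame` of class `qpcr_plate` with columns `sample_id`,
#'   `well`, `dye` (`"target"`/`"reference"`), `ct`; calibrator id stored in
#'   `attr(, "calibrator")` and `max_cycles` in `attr(, "max_cycles")`.
#' @export
simulate_qpcr_plate <- function(copy_numbers, efficiency = 1, base_ct = 25,
                                ct_noise_sd = 0.15, max_cycles = 40,
                                calibrator = NULL, seed = 1) {
  stopifnot(all(copy_numbers %in% 0:2))
  n <- length(copy_numbers)
  if (is.null(calibrator)) {
    calibrator <- which(copy_numbers == 2L)[1]
    if (is.na(calibrator)) stop("no two-copy sample available as calibrator")
  }
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ref_ct <- base_ct + stats::rnorm(3, 0, ct_noise_sd)
      if (copy_numbers[i] > 0) {
        tgt_mu <- base_ct - log2(copy_numbers[i] / 2) / efficiency
        tgt_ct <- pmin(tgt_mu + stats::rnorm(3, 0, ct_noise_sd), max_cycles)
      } else {
        tgt_ct <- rep(max_cycles, 3)
      }
      rows[[i]] <- data.frame(
        sample_id = ids[i],
        well = paste0(ids[i], c("t1", "t2", "t3", "r1", "r2", "r3")),
        dye = rep(c("target", "reference"), each = 3),
        ct = c(tgt_ct, ref_ct))
    }
    plate <- do.call(rbind, rows)
    rownames(plate) <- NULL
    attr(plate, "calibrator") <- ids[calibrator]
    attr(plate, "max_cycles") <- max_cycles
    attr(plate, "truth") <- copy_numbers
    class(plate) <- c("qpcr_plate", "data.frame")
    plate
  })
}

# mean Ct of a triplicate after discarding wells > 1.5 cycles from the median
triplicate_mean <- function(ct) {
  ct <- ct[!is.na(ct)]
  if (!length(ct)) return(NA_real_)
  keep <- abs(ct - stats::median(ct)) <= 1.5
  mean(ct[keep])
}

#' Relative quantification (2^-ddCt) from a qPCR plate
#'
#' Per sample, `dCt = mean(Ct_target) - mean(Ct_reference)`;
#' `ddCt = dCt - dCt_calibrator`; `RQ = 2^-ddCt`. Triplicates are averaged
#' after discarding wells more than 1.5 cycles from their triplicate median.
#' Samples whose target wells all sit at the no-amplification sentinel get
#' `RQ = 0`; samples without reference amplification are flagged failed and
#' get `RQ = NA`.
#'
#' @param plate a `qpcr_plate` (or any data.frame with the same columns).
#' @param calibrator calibrator sample id; defaults to `attr(plate,
#'   "calibrator")`.
#' @param max_cycles sentinel Ct; defaults to `attr(plate, "max_cycles")`
#'   or 40.
#' @return `data.frame` with columns `sample_id`, `dct`, `ddct`, `rq`,
#'   `flag` (`"ok"`, `"no_target_amplification"`, `"failed_reference"`).
#' @export
delta_delta_ct <- function(plate, calibrator = attr(plate, "calibrator"),
                           max_cycles = attr(plate, "max_cycles")) {
  if (is.null(max_cycles)) max_cycles <- 40
  if (is.null(calibrator)) stop("calibrator sample id required")
  stopifnot(all(c("sample_id", "dye", "ct") %in% names(plate)))
  ids <- unique(plate$sample_id)
  res <- data.frame(sample_id = ids, dct = NA_real_, ddct = NA_real_,
                    rq = NA_real_, flag = "ok", stringsAsFactors = FALSE)
  sentinel <- function(ct) is.na(ct) | ct >= max_cycles - 1e-9
  for (i in seq_along(ids)) {
    sub <- plate[plate$sample_id == ids[i], ]
    tgt <- sub$ct[sub$dye == "target"]
    ref <- sub$ct[sub$dye == "reference"]
    if (all(sentinel(ref))) {
      res$flag[i] <- "failed_reference"
      next
    }
    if (all(sentinel(tgt))) {
      res$flag[i] <- "no_target_amplification"
      res$rq[i] <- 0
      next
    }
    res$dct[i] <- triplicate_mean(tgt) - triplicate_mean(ref)
  }
  cal <- res$dct[res$sample_id == calibrator]
  if (!length(cal) || is.na(cal)) {
    stop("calibrator sample must have both dyes amplified")
  }
  ok <- res$flag == "ok"
  res$ddct[ok] <- res$dct[ok] - cal
  res$rq[ok] <- 2^(-res$ddct[ok])
  res
}

#' Call deletion-locus copy number from relative quantification values
#'
#' Estimated copies = `2 * RQ` rounded to the nearest of 0, 1, 2 with the
#' boundaries at 0.5 and 1.5 rounding half up; estimates above 2.5 are called
#' 2 but flagged out-of-range.
#'
#' @param rq numeric RQ values (`NA` allowed for failed samples).
#' @return `data.frame` with columns `rq`, `copies`, `flag`.
#' @export
call_copy_number <- function(rq) {
  stopifnot(all(rq >= 0, na.rm = TRUE))
  est <- 2 * rq
  copies <- ifelse(est < 0.5, 0L, ifelse(est < 1.5, 1L, 2L))
  flag <- ifelse(is.na(rq), "failed",
                 ifelse(est > 2.5, "out_of_range", "ok"))
  copies[is.na(rq)] <- NA_integer_
  data.frame(rq = rq, copies = copies, flag = flag)
}
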