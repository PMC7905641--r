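# Per-sample IQR-outlier thresholds and window-level mosaic state calls.

#' Derive per-sample IQR outlier thresholds
#'
#' Thresholds are computed from the sample's own windows, preserving
#' sample independence. Over eligible windows (probe minimum met, BAF SD
#' defined, and by default autosomes only, since single-copy X/Y in males
#' have no AB band and would corrupt the quartiles):
#' * BAF-SD upper threshold: `q3 + 1.5 * IQR` of window BAF SD,
#' * LRR lower threshold (deletion side): `q1 - 1.5 * IQR` of window mean LRR,
#' * LRR upper threshold (duplication side): `q3 + 1.5 * IQR` of window mean
#'   LRR.
#'
#' Quartiles are linear-interpolation quartiles between order statistics
#' (type 7).
#'
#' @param gw a `genome_windows` object.
#' @param min_probes minimum probes for a window to be eligible (default 20).
#' @param exclude_chroms chromosomes excluded from threshold derivation and
#'   calling (default X and Y).
#' @return a `threshold_set`: list with the quartiles, IQRs and the derived
#'   cutoffs `baf_sd_hi`, `lrr_lo`, `lrr_hi`, plus `n_eligible`.
#' @export
derive_thresholds <- function(gw, min_probes = 20L, exclude_chroms = c("X", "Y")) {
  w <- eligible_windows(gw, min_probes, exclude_chroms)
  if (nrow(w) < 4L)
    stop(sprintf("only %d eligible windows; at least 4 required to derive quartile thresholds",
                 nrow(w)))
  bq <- quartiles(w$baf_sd_het)
  lq <- quartiles(w$avg_lrr)
  b_iqr <- bq[2] - bq[1]
  l_iqr <- lq[2] - lq[1]
  structure(list(
    baf_sd_q1 = bq[1], baf_sd_q3 = bq[2], baf_sd_iqr = b_iqr,
    lrr_q1 = lq[1], lrr_q3 = lq[2], lrr_iqr = l_iqr,
    baf_sd_hi = bq[2] + 1.5 * b_iqr,
    lrr_lo = lq[1] - 1.5 * l_iqr,
    lrr_hi = lq[2] + 1.5 * l_iqr,
    n_eligible = nrow(w),
    min_probes = as.integer(min_probes),
    exclude_chroms = exclude_chroms
  ), class = "threshold_set")
}

eligible_windows <- function(gw, min_probes, exclude_chroms) {
  gw$windows[n_probes >= min_probes & !is.na(baf_sd_het) &
               !as.character(chrom) %in% exclude_chroms]
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set> from %d windows\n",
                     "  BAF SD: q1 %.4f q3 %.4f -> outlier above %.4f\n",
                     "  LRR:    q1 %.4f q3 %.4f -> DEL below %.4f, DUP above %.4f\n"),
              x$n_eligible, x$baf_sd_q1, x$baf_sd_q3, x$baf_sd_hi,
              x$lrr_q1, x$lrr_q3, x$lrr_lo, x$lrr_hi))
  invisible(x)
}

#' Classify windows into mosaic states
#'
#' A window is a candidate only when its BAF SD strictly exceeds the BAF-SD
#' outlier threshold (allelic imbalance has split the AB band). The mean LRR
#' then resolves the copy-number direction:
#' * `DEL`: mean LRR strictly below the low LRR threshold,
#' * `DUP`: mean LRR strictly above the high LRR threshold,
#' * `CNLOH`: mean LRR inside the LRR thresholds (allelic imbalance with no
#'   intensity shift, i.e. copy-neutral LOH),
#' * `NORMAL` otherwise. Ties at a threshold are conservative (`NORMAL`).
#'
#' @param gw a `genome_windows` object.
#' @param thresholds a `threshold_set` from [derive_thresholds()].
#' @return a `data.table` of windows with added columns `eligible`, `state`,
#'   `passed` (state is not `NORMAL`), `clearing_ratio` and `lrr_delta`
#'   (mean LRR minus genome-wide mean LRR, an annotation).
#' @export
classify_windows <- function(gw, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  w <- data.table::copy(gw$windows)
  w[, eligible := n_probes >= thresholds$min_probes & !is.na(baf_sd_het) &
      !as.character(chrom) %in% thresholds$exclude_chroms]
  w[, state := "NORMAL"]
  # a candidate window must carry actual deviating-band evidence: BAF SD can
  # exceed the threshold on AB-band probes alone when few hets are present
  hit <- w$eligible & w$baf_sd_het > thresholds$baf_sd_hi &
    (w$n_ab_low + w$n_ab_high) >= 1L
  w[hit & avg_lrr < thresholds$lrr_lo, state := "DEL"]
  w[hit & avg_lrr > thresholds$lrr_hi, state := "DUP"]
  w[hit & state == "NORMAL", state := "CNLOH"]
  w[, passed := state != "NORMAL"]
  w[, clearing_ratio := clearing_ratio(n_ab, n_ab_low, n_ab_high)]
  w[, lrr_delta := avg_lrr - gw$genome_avg_lrr]
  w[]
}

#' AB clearing ratio of a window
#'
#' Ratio of deviating heterozygous observations (BAF in 0.1-0.4 or 0.6-0.9)
#' to proper heterozygous observations (BAF in 0.4-0.6). High values mean
#' the 0.5 AB band has "cleared" into the displaced mosaic bands. The ratio
#' is `+Inf` when deviating probes exist but the AB band is empty (complete
#' clearing) and 0 when all three counts are zero.
#'
#' @param n_ab,n_ab_low,n_ab_high per-window band counts (vectorized).
#' @return numeric vector of ratios in `[0, Inf]`.
#' @examples
#' clearing_ratio(15, 16, 16)  # ~2.13, passes the curation threshold of 2
#' @export
clearing_ratio <- function(n_ab, n_ab_low, n_ab_high) {
  dev <- n_ab_low + n_ab_high
  out <- ifelse(n_ab > 0, dev / n_ab, ifelse(dev > 0, Inf, 0))
  as.numeric(out)
}

#' Sample-level quality control on genome-wide BAF noise
#'
#' A usable sample must have an acceptably low genome-wide standard
#' deviation of BAF inside (0.1, 0.9): a sample whose heterozygous cloud is
#' diffuse everywhere cannot support windowed outlier detection. Failing
#' samples produce no calls but a full QC record.
#'
#' @param gw a `genome_windows` object.
#' @param max_baf_sd QC cutoff on the genome-wide BAF SD (default 0.20).
#' @return a `sample_qc` list: `genome_baf_sd`, `qc_threshold`, `qc_pass`
#'   and a human-readable `reason` when failing.
#' @export
qc_sample <- function(gw, max_baf_sd = 0.20) {
  sd_val <- gw$genome_baf_sd
  if (is.na(sd_val)) {
    res <- list(genome_baf_sd = NA_real_, qc_threshold = max_baf_sd,
                qc_pass = FALSE,
                reason = "fewer than 2 probes with BAF in (0.1, 0.9); QC indeterminate")
  } else if (sd_val <= max_baf_sd) {
    res <- list(genome_baf_sd = sd_val, qc_threshold = max_baf_sd,
                qc_pass = TRUE, reason = NA_character_)
  } else {
    res <- list(genome_baf_sd = sd_val, qc_threshold = max_baf_sd,
                qc_pass = FALSE,
                reason = sprintf("genome-wide BAF SD %.3f exceeds %.3f", sd_val, max_baf_sd))
  }
  structure(res, class = "sample_qc")
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("<sample_qc> genome BAF SD %s (cutoff %.3f): %s\n",
              if (is.na(x$genome_baf_sd)) "NA" else sprintf("%.4f", x$genome_baf_sd),
              x$qc_threshold, if (x$qc_pass) "PASS" else paste("FAIL -", x$reason)))
  invisible(x)
}
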