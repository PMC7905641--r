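# Fixed-tile windowed tallies of BAF genotype bands and LRR statistics.

.BAF_BINS <- c(0, 0.1, 0.4, 0.6, 0.9, 1)
.BAF_BIN_LABELS <- c("HOM_LOW", "AB_LOW", "AB", "AB_HIGH", "HOM_HIGH")

#' Assign BAF values to genotype bands
#'
#' The five bands used throughout are (0-0.1), (0.1-0.4), (0.4-0.6),
#' (0.6-0.9) and (0.9-1): homozygous tails, the two mosaic-deviation ranges,
#' and the proper heterozygous (AB) band centred on 0.5. Bins are half-open
#' `[lo, hi)` except the top bin, which is closed at 1; with noisy signal the
#' choice of closure at exact boundaries has measure-zero effect.
#'
#' @param baf numeric vector of B-allele frequencies in `[0, 1]`.
#' @return factor with levels `HOM_LOW`, `AB_LOW`, `AB`, `AB_HIGH`,
#'   `HOM_HIGH`.
#' @examples
#' bin_baf(c(0.05, 0.25, 0.5, 0.75, 1.0))
#' @export
bin_baf <- function(baf) {
  if (any(!is.finite(baf) | baf < 0 | baf > 1))
    stop("baf values must lie in [0, 1]")
  cut(baf, breaks = .BAF_BINS, labels = .BAF_BIN_LABELS,
      right = FALSE, include.lowest = TRUE)
}

# deviating het ranges: AB_LOW union AB_HIGH, i.e. [0.1, 0.4) u [0.6, 0.9)
.is_dev <- function(baf) (baf >= 0.1 & baf < 0.4) | (baf >= 0.6 & baf < 0.9)
# strict open interval used for the BAF-SD statistic
.is_het <- function(baf) baf > 0.1 & baf < 0.9

#' Tally per-window BAF-band counts and LRR statistics
#'
#' Scans a sorted track in fixed non-overlapping genomic tiles
#' (`[k*window_bp + 1, (k+1)*window_bp]` on each chromosome, default 1 Mb)
#' and computes, per occupied window: the counts of probes per BAF band, the
#' mean LRR, the population standard deviation of BAF restricted to the open
#' interval (0.1, 0.9), and the positions of the first and last probe in the
#' deviating ranges. Fixed tiles make windows comparable across samples; the
#' pass is a single linear scan so runtime is linear in probe count.
#'
#' @param track a sorted `signal_track`.
#' @param window_bp window (tile) size in bp, default 1,000,000.
#' @return a `genome_windows` object: list with `sample_id`, a `windows`
#'   `data.table` (one row per occupied window), `genome_avg_lrr` (mean LRR
#'   over all probes) and `genome_baf_sd` (population SD of BAF in
#'   (0.1, 0.9) over all probes).
#' @export
scan_windows <- function(track, window_bp = 1e6L) {
  stopifnot(inherits(track, "signal_track"))
  if (!isTRUE(track$sorted))
    stop("track must be sorted; call ensure_sorted() first")
  p <- track$probes
  if (nrow(p) == 0L) stop("empty track")

  bins <- bin_baf(p$baf)
  wdt <- data.table::data.table(
    chrom = p$chrom,
    tile = (p$pos - 1L) %/% as.integer(window_bp),
    pos = p$pos, baf = p$baf, lrr = p$lrr, bin = bins)

  win <- wdt[, {
    het <- .is_het(baf)
    dev <- .is_dev(baf)
    dp <- pos[dev]
    list(n_ab = sum(bin == "AB"),
         n_ab_low = sum(bin == "AB_LOW"),
         n_ab_high = sum(bin == "AB_HIGH"),
         n_hom = sum(bin == "HOM_LOW" | bin == "HOM_HIGH"),
         n_probes = .N,
         avg_lrr = mean(lrr),
         baf_sd_het = pop_sd(baf[het]),
         first_dev_pos = if (length(dp)) dp[1L] else NA_integer_,
         last_dev_pos = if (length(dp)) dp[length(dp)] else NA_integer_)
  }, by = .(chrom, tile)]

  win[, window_start := tile * as.integer(window_bp) + 1L]
  win[, window_end := (tile + 1L) * as.integer(window_bp)]
  win[, terminal := tile == max(tile), by = chrom]
  win[, tile := NULL]
  data.table::setcolorder(win, c("chrom", "window_start", "window_end"))
  data.table::setorder(win, chrom, window_start)

  het_all <- .is_het(p$baf)
  structure(list(sample_id = track$sample_id,
                 windows = win,
                 window_bp = as.integer(window_bp),
                 genome_avg_lrr = mean(p$lrr),
                 genome_baf_sd = pop_sd(p$baf[het_all]),
                 genome_het_ab_frac = mean(p$baf > 0.4 & p$baf < 0.6),
                 n_probes = nrow(p)),
            class = "genome_windows")
}

#' @export
print.genome_windows <- function(x, ...) {
  cat(sprintf(paste0("<genome_windows> sample '%s': %d windows (%d kb tiles),",
                     " %d probes\n  genome avg LRR %.4f, genome BAF SD %s\n"),
              x$sample_id, nrow(x$windows), x$window_bp %/% 1000L, x$n_probes,
              x$genome_avg_lrr,
              if (is.na(x$genome_baf_sd)) "NA" else sprintf("%.4f", x$genome_baf_sd)))
  invisible(x)
}

#' Write the per-window report
#'
#' One row per occupied window with the classic report fields:
#' `CHIP REGION AB ABLow ABHigh AAorBB AvgLRR BAF_SD`.
#'
#' @param gw a `genome_windows` object.
#' @param path output path.
#' @export
write_window_report <- function(gw, path) {
  w <- gw$windows
  out <- w[, .(CHIP = gw$sample_id,
               REGION = sprintf("%s:%d-%d", as.character(chrom),
                                window_start, window_end),
               AB = n_ab, ABLow = n_ab_low, ABHigh = n_ab_high,
               AAorBB = n_hom, AvgLRR = avg_lrr, BAF_SD = baf_sd_het)]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
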