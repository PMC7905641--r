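# End-to-end detection pipeline, run configuration and plotting.

#' Detection run configuration
#'
#' Collects every tunable of the pipeline with its default. Any field can
#' be overridden; invalid combinations fail fast.
#'
#' @param window_bp scan window (tile) size in bp (default 1e6).
#' @param min_probes_per_window eligibility minimum per window (default 20).
#' @param gap_fraction merge gap tolerance as a fraction of combined span
#'   (default 0.2).
#' @param min_len_bp minimum event span for the high-confidence stratum
#'   (default 3e6).
#' @param qc_baf_sd_max sample QC cutoff on genome-wide BAF SD (default 0.20).
#' @param clearing_ratio_min clearing-ratio threshold for the `curated`
#'   annotation flag on calls (default 2); annotation only, calls are not
#'   removed on this criterion.
#' @param homdel_mode `"approx"` (default), `"external"` or `"off"`.
#' @param homdel_path interval file for `homdel_mode = "external"`.
#' @param homdel_lrr_max,homdel_het_density_frac approximation-subroutine
#'   cutoffs (defaults -2.0 and 0.10).
#' @param exclude_chroms chromosomes excluded from thresholds and calling
#'   (default X, Y).
#' @param max_raw_events raw merged events above which a sample is flagged
#'   noisy and its calls suppressed (default 50). The IQR boxplot rule
#'   flags roughly 0.5-0.7% of windows on a clean genome-wide scan
#'   (~15-20 single-window candidates over ~2,900 windows), so the guard
#'   sits well above that null expectation.
#' @return a `run_config` list.
#' @export
run_config <- function(window_bp = 1e6, min_probes_per_window = 20L,
                       gap_fraction = 0.2, min_len_bp = 3e6,
                       qc_baf_sd_max = 0.20, clearing_ratio_min = 2,
                       homdel_mode = c("approx", "external", "off"),
                       homdel_path = NULL, homdel_lrr_max = -2.0,
                       homdel_het_density_frac = 0.10,
                       exclude_chroms = c("X", "Y"),
                       max_raw_events = 50L) {
  homdel_mode <- match.arg(homdel_mode)
  stopifnot(window_bp > 0, min_probes_per_window > 0, gap_fraction > 0,
            min_len_bp > 0, qc_baf_sd_max > 0, clearing_ratio_min > 0,
            max_raw_events > 0)
  if (homdel_mode == "external" && is.null(homdel_path))
    stop("homdel_mode = 'external' requires homdel_path")
  structure(list(window_bp = window_bp,
                 min_probes_per_window = as.integer(min_probes_per_window),
                 gap_fraction = gap_fraction, min_len_bp = min_len_bp,
                 qc_baf_sd_max = qc_baf_sd_max,
                 clearing_ratio_min = clearing_ratio_min,
                 homdel_mode = homdel_mode, homdel_path = homdel_path,
                 homdel_lrr_max = homdel_lrr_max,
                 homdel_het_density_frac = homdel_het_density_frac,
                 exclude_chroms = exclude_chroms,
                 max_raw_events = as.integer(max_raw_events)),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys are the argument names of [run_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file (flags win over file).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' Run the full mosaic detection pipeline on one sample
#'
#' Sort, window-scan, QC, derive per-sample IQR thresholds, classify
#' windows, merge, refine breakpoints, and apply the filter cascade
#' (homozygous-deletion exclusion, then the minimum-size stratum). A sample
#' failing QC, or producing more raw merged events than `max_raw_events`
#' (a noise signature), yields no calls but a full report.
#'
#' @param track a `signal_track` (sorted or not).
#' @param config a `run_config`.
#' @param homdel optional pre-loaded homozygous-deletion interval table;
#'   overrides `config$homdel_path`.
#' @return a `mosaic_result` list: `sample_id`, `qc`, `thresholds`,
#'   `windows` (classified), `calls` (final: homdel-filtered, annotated with
#'   `size_pass` and `curated`), `removed` (calls cut by the homdel filter),
#'   `tier`, `noisy`, and `cascade` (stage counts in filter order).
#' @export
detect_mosaic <- function(track, config = run_config(), homdel = NULL) {
  stopifnot(inherits(track, "signal_track"), inherits(config, "run_config"))
  track <- ensure_sorted(track)
  gw <- scan_windows(track, window_bp = config$window_bp)
  qc <- qc_sample(gw, max_baf_sd = config$qc_baf_sd_max)

  empty <- function(reason, thresholds = NULL, windows = NULL, noisy = FALSE) {
    structure(list(sample_id = track$sample_id, qc = qc,
                   thresholds = thresholds, windows = windows,
                   calls = .final_calls(.empty_calls()),
                   removed = .empty_calls()[, filter_reason := character()][],
                   tier = "none", noisy = noisy, no_call_reason = reason,
                   cascade = c(raw = 0L, post_homdel = 0L, ge_min_len = 0L)),
              class = "mosaic_result")
  }
  if (!qc$qc_pass) return(empty(paste("QC fail:", qc$reason)))

  thresholds <- derive_thresholds(gw, min_probes = config$min_probes_per_window,
                                  exclude_chroms = config$exclude_chroms)
  wc <- classify_windows(gw, thresholds)
  raw <- merge_windows(wc, gap_fraction = config$gap_fraction)
  if (nrow(raw) > config$max_raw_events)
    return(empty(sprintf("noisy sample: %d raw merged events (max %d)",
                         nrow(raw), config$max_raw_events),
                 thresholds, wc, noisy = TRUE))

  calls <- refine_breakpoints(raw, track)
  if (config$homdel_mode == "external" && is.null(homdel))
    homdel <- read_homdel_intervals(config$homdel_path)
  if (config$homdel_mode == "off") {
    fh <- list(calls = calls,
               removed = .empty_calls()[, filter_reason := character()][])
  } else {
    fh <- filter_homdel(calls, track, homdel = homdel,
                        lrr_max = config$homdel_lrr_max,
                        het_density_frac = config$homdel_het_density_frac)
  }
  fs <- filter_size(fh$calls, min_len_bp = config$min_len_bp)
  final <- fs$calls
  if (nrow(final)) final[, curated := clearing_ratio_min >= config$clearing_ratio_min]
  else final <- .final_calls(final)

  structure(list(sample_id = track$sample_id, qc = qc,
                 thresholds = thresholds, windows = wc,
                 calls = final[], removed = fh$removed,
                 tier = fs$tier, noisy = FALSE, no_call_reason = NA_character_,
                 cascade = c(raw = nrow(raw), post_homdel = nrow(fh$calls),
                             ge_min_len = fs$n_ge_min)),
            class = "mosaic_result")
}

.final_calls <- function(calls) {
  if (!"size_pass" %in% names(calls)) calls[, size_pass := logical(0)]
  if (!"curated" %in% names(calls)) calls[, curated := logical(0)]
  calls[]
}

#' @export
print.mosaic_result <- function(x, ...) {
  cat(sprintf("<mosaic_result> sample '%s'\n", x$sample_id))
  print(x$qc)
  if (!is.na(x$no_call_reason)) {
    cat("  no calls:", x$no_call_reason, "\n")
  } else {
    cat(sprintf("  cascade: %d raw -> %d post-homdel -> %d >= min length (tier %s)\n",
                x$cascade["raw"], x$cascade["post_homdel"],
                x$cascade["ge_min_len"], x$tier))
    if (nrow(x$calls)) print(x$calls)
  }
  invisible(x)
}

#' Run detection over a batch of signal files
#'
#' Samples are processed independently; a hard error in one sample is
#' caught, reported and the batch continues.
#'
#' @param paths character vector of signal file paths.
#' @param config a `run_config`.
#' @param probe_map optional shared probe map.
#' @return named list of `mosaic_result` (or `try-error` strings for failed
#'   samples), plus an attribute `cascade` with batch-level stage totals.
#' @export
run_detect <- function(paths, config = run_config(), probe_map = NULL) {
  if (length(paths) == 0L) stop("no signal files")
  homdel <- if (config$homdel_mode == "external")
    read_homdel_intervals(config$homdel_path) else NULL
  results <- lapply(paths, function(pp) {
    tryCatch({
      tr <- parse_signal_file(pp, probe_map = probe_map)
      detect_mosaic(tr, config, homdel = homdel)
    }, error = function(e) structure(conditionMessage(e), class = "sample_error"))
  })
  names(results) <- vapply(paths, function(pp) sub("\\.[^.]*$", "", basename(pp)), "")
  ok <- vapply(results, inherits, TRUE, what = "mosaic_result")
  casc <- Reduce(`+`, lapply(results[ok], `[[`, "cascade"),
                 c(raw = 0L, post_homdel = 0L, ge_min_len = 0L))
  attr(results, "cascade") <- casc
  results
}

#' Genome-wide LRR/BAF plot with highlighted calls
#'
#' Two stacked panels (LRR above, BAF below) on a linear genome axis with
#' alternating chromosome colours, Manhattan-style; call spans are shaded.
#'
#' @param track a sorted `signal_track`.
#' @param calls optional `data.table` of calls to highlight.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param thin plot at most this many probes (deterministic stride),
#'   default 100,000.
#' @return invisibly, the per-chromosome genome-axis offsets.
#' @export
plot_sample <- function(track, calls = NULL, file = NULL, thin = 1e5) {
  track <- ensure_sorted(track)
  p <- track$probes
  if (nrow(p) > thin) p <- p[seq(1L, nrow(p), length.out = thin)]
  sizes <- p[, .(len = max(pos)), by = chrom]
  sizes[, offset := data.table::shift(cumsum(as.numeric(len)), fill = 0)]
  p <- merge(p, sizes[, .(chrom, offset)], by = "chrom", sort = FALSE)
  p[, x := offset + pos]
  p[, col := c("grey25", "grey60")[(as.integer(chrom) %% 2L) + 1L]]

  if (!is.null(file)) {
    grDevices::png(file, width = 1400, height = 700)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  shade <- function() {
    if (!is.null(calls) && nrow(calls)) {
      cc <- merge(data.table::as.data.table(calls), sizes[, .(chrom, offset)],
                  by = "chrom", sort = FALSE)
      graphics::rect(cc$offset + cc$start_bp, graphics::par("usr")[3],
                     cc$offset + cc$end_bp, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("firebrick", 0.25), border = NA)
    }
  }
  graphics::plot(p$x, p$lrr, pch = ".", col = p$col, ylim = c(-2, 2),
                 xlab = "", ylab = "LRR", main = track$sample_id, xaxt = "n")
  shade()
  graphics::abline(h = 0, col = "steelblue")
  graphics::plot(p$x, p$baf, pch = ".", col = p$col, ylim = c(0, 1),
                 xlab = "genome position", ylab = "BAF", xaxt = "n")
  shade()
  graphics::axis(1, at = sizes$offset + sizes$len / 2,
                 labels = as.character(sizes$chrom), tick = FALSE, cex.axis = 0.7)
  invisible(sizes)
}

#' Write a QC / run report as JSON
#'
#' @param result a `mosaic_result`.
#' @param path output JSON path.
#' @export
write_qc_report <- function(result, path) {
  rep <- list(sample_id = result$sample_id,
              qc = result$qc[c("genome_baf_sd", "qc_threshold", "qc_pass", "reason")],
              thresholds = if (!is.null(result$thresholds))
                unclass(result$thresholds)[c("baf_sd_hi", "lrr_lo", "lrr_hi",
                                             "n_eligible")] else NULL,
              noisy = result$noisy,
              tier = result$tier,
              cascade = as.list(result$cascade),
              n_calls = nrow(result$calls))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
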