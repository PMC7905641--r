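# Merging threshold-passing windows into events, breakpoint refinement and
# the filtering cascade.

#' Merge threshold-passing windows into raw events
#'
#' Two-stage merge in the spirit of fragment-cleaning tools for CNV calls:
#' 1. runs of adjacent same-state passing windows on one chromosome collapse
#'    into a single event;
#' 2. two same-state events are further merged when the intervening gap is
#'    at most `gap_fraction` of the combined span (gap included), iterated
#'    to a fixpoint.
#' Events never merge across chromosomes or across states (a deletion
#' touching a duplication stays two events).
#'
#' @param window_calls classified windows from [classify_windows()], sorted.
#' @param gap_fraction maximum gap-to-span ratio for the second-stage merge
#'   (default 0.2).
#' @return `data.table` of raw events with window-span coordinates
#'   (`span_start`, `span_end`), `state`, `n_windows`, `clearing_ratio_min`
#'   and summed band counts.
#' @export
merge_windows <- function(window_calls, gap_fraction = 0.2) {
  w <- window_calls[passed == TRUE]
  if (nrow(w) == 0L) return(.empty_events())
  data.table::setorder(w, chrom, window_start)
  # stage 1: collapse runs of adjacent same-state windows
  w[, run := cumsum(c(1L, (as.character(chrom)[-1] != as.character(chrom)[-.N]) |
                        (state[-1] != state[-.N]) |
                        (window_start[-1] != window_end[-.N] + 1L)))]
  ev <- w[, .(chrom = chrom[1L], state = state[1L],
              span_start = min(window_start), span_end = max(window_end),
              n_windows = .N,
              n_ab = sum(n_ab), n_ab_low = sum(n_ab_low),
              n_ab_high = sum(n_ab_high),
              clearing_ratio_min = min(clearing_ratio)),
          by = run][, run := NULL]
  # stage 2: gap-tolerant merge to fixpoint
  repeat {
    data.table::setorder(ev, chrom, span_start)
    if (nrow(ev) < 2L) break
    same <- as.character(ev$chrom)[-1] == as.character(ev$chrom)[-nrow(ev)] &
      ev$state[-1] == ev$state[-nrow(ev)]
    gap <- ev$span_start[-1] - ev$span_end[-nrow(ev)] - 1L
    span <- ev$span_end[-1] - ev$span_start[-nrow(ev)] + 1L
    mergeable <- which(same & gap <= gap_fraction * span)
    if (length(mergeable) == 0L) break
    i <- mergeable[1L]
    ev$span_end[i] <- ev$span_end[i + 1L]
    ev$n_windows[i] <- ev$n_windows[i] + ev$n_windows[i + 1L]
    ev$n_ab[i] <- ev$n_ab[i] + ev$n_ab[i + 1L]
    ev$n_ab_low[i] <- ev$n_ab_low[i] + ev$n_ab_low[i + 1L]
    ev$n_ab_high[i] <- ev$n_ab_high[i] + ev$n_ab_high[i + 1L]
    ev$clearing_ratio_min[i] <- min(ev$clearing_ratio_min[i],
                                    ev$clearing_ratio_min[i + 1L])
    ev <- ev[-(i + 1L)]
  }
  ev[]
}

.empty_events <- function() {
  data.table::data.table(chrom = chrom_factor(character()), state = character(),
                         span_start = integer(), span_end = integer(),
                         n_windows = integer(), n_ab = integer(),
                         n_ab_low = integer(), n_ab_high = integer(),
                         clearing_ratio_min = numeric())
}

#' Refine event breakpoints to the first and last mosaic evidence
#'
#' Window-span coordinates are coarse (tile-aligned); the reported
#' breakpoints are the positions of the first and last probe with BAF in the
#' deviating ranges (0.1-0.4 or 0.6-0.9) inside the merged span. Also
#' estimates the B-deviation (median displacement of in-span heterozygous
#' BAF from 0.5) and converts it to a cell-fraction estimate under the
#' allelic mixture model for the event's state (see
#' [estimate_cell_fraction()]).
#'
#' @param events raw events from [merge_windows()].
#' @param track the sorted `signal_track` the windows came from.
#' @return `data.table` of refined calls: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `length_bp`, `state`, `n_windows`, `n_dev_probes`,
#'   `clearing_ratio_min`, `bdev`, `cell_fraction`.
#' @export
refine_breakpoints <- function(events, track) {
  stopifnot(inherits(track, "signal_track"), isTRUE(track$sorted))
  p <- track$probes
  n <- nrow(events)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e <- events[i]
    span <- p[chrom == e$chrom & pos >= e$span_start & pos <= e$span_end]
    dev <- span[.is_dev(baf)]
    if (nrow(dev) == 0L)
      stop("no deviating probe inside a passing event span; inconsistent inputs")
    start_bp <- dev$pos[1L]
    end_bp <- dev$pos[nrow(dev)]
    inside <- span[pos >= start_bp & pos <= end_bp]
    het <- inside$baf[.is_het(inside$baf)]
    bdev <- if (length(het)) stats::median(abs(het - 0.5)) else NA_real_
    out[[i]] <- data.table::data.table(
      sample_id = track$sample_id, chrom = e$chrom,
      start_bp = start_bp, end_bp = end_bp,
      length_bp = end_bp - start_bp + 1L,
      state = e$state, n_windows = e$n_windows,
      n_dev_probes = sum(.is_dev(inside$baf)),
      clearing_ratio_min = e$clearing_ratio_min,
      bdev = bdev,
      cell_fraction = estimate_cell_fraction(e$state, bdev))
  }
  calls <- data.table::rbindlist(out)
  if (nrow(calls)) data.table::setorder(calls, chrom, start_bp)
  else calls <- .empty_calls(track$sample_id)
  calls[]
}

.empty_calls <- function(sample_id = character()) {
  data.table::data.table(sample_id = character(), chrom = chrom_factor(character()),
                         start_bp = integer(), end_bp = integer(),
                         length_bp = integer(), state = character(),
                         n_windows = integer(), n_dev_probes = integer(),
                         clearing_ratio_min = numeric(), bdev = numeric(),
                         cell_fraction = numeric())
}

#' Cell fraction implied by an observed B-deviation
#'
#' Inverts the allelic mixture model: for a cell fraction `f`, the
#' heterozygous band displacement from 0.5 is `f / (2 * (2 - f))` for a
#' deletion, `f / (2 * (2 + f))` for a duplication and `f / 2` for
#' copy-neutral LOH. A crude moment estimate; deviations beyond the
#' single-copy limit are clamped to 1.
#'
#' @param state `"DEL"`, `"DUP"` or `"CNLOH"`.
#' @param bdev observed B-deviation (median `|BAF - 0.5|` of het probes).
#' @return estimated cell fraction in `[0, 1]`.
#' @export
estimate_cell_fraction <- function(state, bdev) {
  if (is.na(bdev)) return(NA_real_)
  f <- switch(state,
              DEL = 4 * bdev / (1 + 2 * bdev),
              DUP = if (bdev >= 0.5) Inf else 4 * bdev / (1 - 2 * bdev),
              CNLOH = 2 * bdev,
              NA_real_)
  if (is.na(f)) return(NA_real_)
  min(max(f, 0), 1)
}

#' Read homozygous-deletion intervals (BED or rawcnv text)
#'
#' Accepts 3+ column BED (0-based half-open; converted to 1-based inclusive)
#' or PennCNV-style rawcnv lines (`chr1:100-200 numsnp=.. cn=0 ..`), keeping
#' only copy-number-0 records in the latter case.
#'
#' @param path path to the interval file.
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_homdel_intervals <- function(path) {
  if (!file.exists(path)) stop(sprintf("interval file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(), end = integer()))
  if (grepl("^\\s*\\S+:\\d+-\\d+", lines[1])) {
    m <- regmatches(lines, regexec("^\\s*(\\S+?):(\\d+)-(\\d+)", lines))
    ok <- lengths(m) == 4L
    cn <- rep(NA_integer_, length(lines))
    has_cn <- grepl("cn=\\d", lines)
    cn[has_cn] <- as.integer(sub(".*cn=(\\d+).*", "\\1", lines[has_cn]))
    keep <- ok & (!has_cn | cn == 0L)
    dt <- data.table::data.table(
      chrom = vapply(m[keep], `[`, "", 2L),
      start = as.integer(vapply(m[keep], `[`, "", 3L)),
      end = as.integer(vapply(m[keep], `[`, "", 4L)))
  } else {
    f <- data.table::fread(text = lines, header = FALSE, sep = "\t")
    if (ncol(f) < 3L) stop("malformed interval file: fewer than 3 columns")
    dt <- data.table::data.table(chrom = as.character(f[[1]]),
                                 start = as.integer(f[[2]]) + 1L,
                                 end = as.integer(f[[3]]))
  }
  dt[, chrom := normalize_chrom(chrom)]
  dt <- dt[!is.na(chrom) & is.finite(start) & is.finite(end) & start <= end]
  dt[]
}

#' Exclude calls caused by homozygous deletions
#'
#' Real homozygous deletions (copy number 0) leave BAF as noise, which can
#' mimic mosaic band splitting and must be excluded. Two modes:
#' * with an external homozygous-deletion callset, any call overlapping an
#'   interval by at least 1 bp is removed;
#' * otherwise an approximation subroutine removes a call when its span
#'   carries the CN0 signature: mean LRR below `lrr_max` (default -2.0,
#'   far beyond any mosaic shift) and a proper-AB probe density below
#'   `het_density_frac` (default 10%) of the sample's genome-wide AB
#'   density (noise, not genotype splitting).
#'
#' @param calls refined calls from [refine_breakpoints()].
#' @param track the sample's sorted `signal_track`.
#' @param homdel optional `data.table` of intervals from
#'   [read_homdel_intervals()] (1-based inclusive).
#' @param lrr_max,het_density_frac approximation-subroutine cutoffs.
#' @return list with `calls` (retained), `removed` (with `filter_reason`).
#' @export
filter_homdel <- function(calls, track, homdel = NULL,
                          lrr_max = -2.0, het_density_frac = 0.10) {
  if (nrow(calls) == 0L)
    return(list(calls = calls, removed = .empty_calls()[, filter_reason := character()][]))
  if (!is.null(homdel) && nrow(homdel) > 0L) {
    q <- GenomicRanges::GRanges(as.character(calls$chrom),
                                IRanges::IRanges(calls$start_bp, calls$end_bp))
    s <- GenomicRanges::GRanges(as.character(homdel$chrom),
                                IRanges::IRanges(homdel$start, homdel$end))
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(q, s)))
    drop <- seq_len(nrow(calls)) %in% hit
    reason <- "overlaps external homozygous-deletion call"
  } else {
    p <- track$probes
    genome_ab <- mean(p$baf > 0.4 & p$baf < 0.6)
    drop <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      span <- p[chrom == calls$chrom[i] & pos >= calls$start_bp[i] &
                  pos <= calls$end_bp[i]]
      span_ab <- mean(span$baf > 0.4 & span$baf < 0.6)
      drop[i] <- mean(span$lrr) < lrr_max &&
        genome_ab > 0 && span_ab < het_density_frac * genome_ab
    }
    reason <- "CN0 signature (approximation subroutine)"
  }
  removed <- calls[drop][, filter_reason := reason]
  list(calls = calls[!drop], removed = removed[])
}

#' Annotate calls with the minimum-size filter and sample tier
#'
#' Calls at or above `min_len_bp` (default 3 Mb) are the high-confidence
#' stratum. The sample tier summarizes how many qualifying calls it has:
#' `none`, `at_least_one_ge3Mb` or `exactly_one_ge3Mb` (strictly one
#' qualifying call, the highest-specificity tier).
#'
#' @param calls refined calls.
#' @param min_len_bp minimum genomic span in bp (default 3,000,000).
#' @return list with `calls` (annotated with logical `size_pass`), `tier`,
#'   and `n_ge_min` (count of qualifying calls).
#' @export
filter_size <- function(calls, min_len_bp = 3e6) {
  calls <- data.table::copy(calls)
  calls[, size_pass := length_bp >= min_len_bp]
  n_big <- sum(calls$size_pass)
  tier <- if (n_big == 0L) "none"
  else if (n_big == 1L) "exactly_one_ge3Mb"
  else "at_least_one_ge3Mb"
  list(calls = calls[], tier = tier, n_ge_min = n_big)
}

#' Summarize a callset across samples
#'
#' Event counts by state, per-sample counts, median and mean event length,
#' and (when a sample sex vector is provided) a 2x2 sex-enrichment table of
#' mosaic-positive status with a two-tailed Fisher exact p-value.
#'
#' @param calls a `data.table` of calls (possibly multiple samples).
#' @param sex optional named character vector (`"M"`/`"F"`) covering the
#'   whole cohort, names are sample ids; samples absent from `calls` count
#'   as mosaic-negative.
#' @return list with `n_events`, `n_samples`, `by_state`,
#'   `median_length_bp`, `mean_length_bp`, and optionally `sex_table`,
#'   `fisher_p`, `pct_male_events`.
#' @export
summarize_callset <- function(calls, sex = NULL) {
  res <- list(
    n_events = nrow(calls),
    n_samples = length(unique(calls$sample_id)),
    by_state = if (nrow(calls)) table(calls$state) else table(character()),
    median_length_bp = if (nrow(calls)) stats::median(as.numeric(calls$length_bp)) else NA_real_,
    mean_length_bp = if (nrow(calls)) mean(as.numeric(calls$length_bp)) else NA_real_
  )
  if (!is.null(sex)) {
    pos <- names(sex) %in% unique(calls$sample_id)
    male <- sex == "M"
    tab <- matrix(c(sum(pos & male), sum(pos & !male),
                    sum(!pos & male), sum(!pos & !male)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("mosaic", "clean"), c("male", "female")))
    res$sex_table <- tab
    res$fisher_p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    res$pct_male_events <- if (any(pos)) 100 * sum(pos & male) / sum(pos) else NA_real_
  }
  res
}
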