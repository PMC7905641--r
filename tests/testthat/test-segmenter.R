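# window_calls rows with just the fields the segmenter consumes
wc_row <- function(chrom, start_mb, end_mb, state, passed = TRUE,
                   n_ab = 10L, n_lo = 20L, n_hi = 20L) {
  data.table::data.table(
    chrom = factor(chrom, levels = c(as.character(1:22), "X", "Y")),
    window_start = as.integer(start_mb * 1e6 + 1),
    window_end = as.integer(end_mb * 1e6),
    state = state, passed = passed,
    n_ab = n_ab, n_ab_low = n_lo, n_ab_high = n_hi,
    clearing_ratio = clearing_ratio(n_ab, n_lo, n_hi))
}

test_that("adjacent same-state windows merge; states and chromosomes never mix", {
  wc <- rbind(wc_row("1", 0, 1, "DEL"), wc_row("1", 1, 2, "DEL"),
              wc_row("1", 2, 3, "DUP"), wc_row("2", 3, 4, "DUP"))
  ev <- merge_windows(wc)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev[state == "DEL", .(span_start, span_end, n_windows)],
               data.table::data.table(span_start = 1L, span_end = 2000000L,
                                      n_windows = 2L))
  expect_equal(as.character(ev$chrom[ev$state == "DUP"]), c("1", "2"))

  # single passing window is an identity merge
  one <- merge_windows(wc_row("5", 10, 11, "CNLOH"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_windows, 1L)
})

test_that("gap merging applies the gap/span fraction rule to fixpoint", {
  # 4 Mb + 4 Mb separated by a 1 Mb gap: 1 <= 0.2 * 9 -> merged
  near <- rbind(wc_row("1", 0, 1, "DEL"), wc_row("1", 1, 2, "DEL"),
                wc_row("1", 2, 3, "DEL"), wc_row("1", 3, 4, "DEL"),
                wc_row("1", 5, 6, "DEL"), wc_row("1", 6, 7, "DEL"),
                wc_row("1", 7, 8, "DEL"), wc_row("1", 8, 9, "DEL"))
  ev <- merge_windows(near, gap_fraction = 0.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$span_start, 1L)
  expect_equal(ev$span_end, 9000000L)
  expect_equal(ev$n_windows, 8L)

  # same events separated by a 3 Mb gap: 3 > 0.2 * 11 -> stays split
  far <- rbind(near[1:4], data.table::copy(near[5:8])[
    , `:=`(window_start = window_start + 2000000L,
           window_end = window_end + 2000000L)])
  ev2 <- merge_windows(far, gap_fraction = 0.2)
  expect_equal(nrow(ev2), 2L)

  # fixpoint: no two remaining same-state neighbours satisfy the rule,
  # and output intervals are non-overlapping in order
  expect_true(all(diff(ev2$span_start) > 0))
  gap <- ev2$span_start[2] - ev2$span_end[1] - 1
  span <- ev2$span_end[2] - ev2$span_start[1] + 1
  expect_gt(gap, 0.2 * span)
  expect_equal(merge_windows(near[0]), merge_windows(near[0]))  # empty in, empty out
})

test_that("breakpoints refine to the first and last deviating probe", {
  pos <- c(1100000, 1250431, 1700000, 2100000, 2871002, 2950000)
  baf <- c(0.50, 0.35, 0.34, 0.66, 0.65, 0.50)  # dev probes at indices 2:5
  tr <- make_track("1", pos, baf, rep(-0.2, 6), sample_id = "bp")
  ev <- data.table::data.table(
    chrom = factor("1", levels = c(as.character(1:22), "X", "Y")),
    state = "DEL", span_start = 1000001L, span_end = 3000000L,
    n_windows = 3L, n_ab = 2L, n_ab_low = 2L, n_ab_high = 2L,
    clearing_ratio_min = 2)
  call <- refine_breakpoints(ev, tr)
  expect_equal(call$start_bp, 1250431L)
  expect_equal(call$end_bp, 2871002L)
  expect_equal(call$n_dev_probes, 4L)
  expect_equal(call$length_bp, 2871002L - 1250431L + 1L)

  # idempotent: refining the refined span returns identical breakpoints
  ev2 <- data.table::copy(ev)[, `:=`(span_start = call$start_bp,
                                     span_end = call$end_bp)]
  call2 <- refine_breakpoints(ev2, tr)
  expect_equal(call2$start_bp, call$start_bp)
  expect_equal(call2$end_bp, call$end_bp)

  # a span with no deviating probe violates the refine contract
  ev3 <- data.table::copy(ev)[, `:=`(span_start = 2900001L, span_end = 3000000L)]
  expect_error(refine_breakpoints(ev3, tr), "deviating")
})

test_that("cell-fraction estimates invert the band model", {
  for (f in c(0.1, 0.3, 0.6, 1.0)) {
    for (st in c("DEL", "DUP", "CNLOH")) {
      if (st == "DUP" && f == 1) next
      b <- expected_bdev(st, f)
      expect_equal(estimate_cell_fraction(st, b), f, tolerance = 1e-9)
    }
  }
  expect_true(is.na(estimate_cell_fraction("DEL", NA_real_)))
  expect_equal(estimate_cell_fraction("DUP", 0.49), 1)  # clamped at 1
})

test_that("external homozygous-deletion intervals exclude overlapping calls", {
  calls <- data.table::data.table(
    sample_id = "s", chrom = factor(c("1", "2"), levels = c(as.character(1:22), "X", "Y")),
    start_bp = c(1000000L, 5000000L), end_bp = c(4000000L, 9000000L),
    length_bp = c(3000001L, 4000001L), state = "DEL", n_windows = 3L,
    n_dev_probes = 100L, clearing_ratio_min = 1, bdev = 0.1, cell_fraction = 0.3)
  tr <- make_track("1", 1, 0.5, 0)  # unused in external mode
  # 1 bp overlap with the first call
  homdel <- data.table::data.table(chrom = "1", start = 4000000L, end = 4100000L)
  out <- filter_homdel(calls, tr, homdel = homdel)
  expect_equal(nrow(out$calls), 1L)
  expect_equal(as.character(out$calls$chrom), "2")
  expect_match(out$removed$filter_reason, "external")

  # BED and rawcnv interval files parse to the same 1-based rows
  fb <- tempfile(fileext = ".bed")
  writeLines("1\t3999999\t4100000", fb)
  expect_equal(read_homdel_intervals(fb),
               data.table::data.table(chrom = "1", start = 4000000L, end = 4100000L))
  fr <- tempfile(fileext = ".rawcnv")
  writeLines(c("chr1:4000000-4100000 numsnp=12 length=100,001 state1,cn=0 s.txt startsnp=a endsnp=b",
               "chr2:1-100 numsnp=5 length=100 state2,cn=1 s.txt startsnp=c endsnp=d"), fr)
  raw <- read_homdel_intervals(fr)
  expect_equal(raw, data.table::data.table(chrom = "1", start = 4000000L, end = 4100000L))
})

test_that("the approximation subroutine removes CN0 signatures and keeps mosaic losses", {
  # simulated copy-number-0 region: deep LRR, BAF reduced to intensity noise
  sim <- simulate_sample(small_params(seed = 31),
                         truth_events("1", 5e6, 12e6, "CN0", 1))
  gw <- scan_windows(sim$track)
  wc <- classify_windows(gw, derive_thresholds(gw))
  raw <- merge_windows(wc)
  expect_gt(nrow(raw), 0)  # the CN0 noise is falsely flagged by the windowing
  calls <- refine_breakpoints(raw, sim$track)
  out <- filter_homdel(calls, sim$track)
  big_kept <- out$calls[length_bp >= 3e6]
  expect_equal(nrow(big_kept), 0L)
  expect_true(any(out$removed$length_bp >= 3e6))

  # a genuine mosaic deletion (mean LRR ~ -0.3) is retained
  sim2 <- simulate_sample(small_params(seed = 32),
                          truth_events("1", 5e6, 12e6, "DEL", 0.4))
  gw2 <- scan_windows(sim2$track)
  calls2 <- refine_breakpoints(merge_windows(classify_windows(gw2, derive_thresholds(gw2))),
                               sim2$track)
  out2 <- filter_homdel(calls2, sim2$track)
  expect_true(any(out2$calls$length_bp >= 3e6 & out2$calls$state == "DEL"))
})

test_that("size filtering assigns sample tiers and keeps cascade monotone", {
  mk <- function(lens_mb) data.table::data.table(
    sample_id = "s", chrom = factor("1", levels = c(as.character(1:22), "X", "Y")),
    start_bp = 1L, end_bp = as.integer(lens_mb * 1e6),
    length_bp = as.integer(lens_mb * 1e6), state = "DEL", n_windows = 1L,
    n_dev_probes = 10L, clearing_ratio_min = 1, bdev = 0.1, cell_fraction = 0.3)
  expect_equal(filter_size(mk(8.5))$tier, "exactly_one_ge3Mb")
  expect_equal(filter_size(mk(c(4, 5)))$tier, "at_least_one_ge3Mb")
  expect_equal(filter_size(mk(c(2, 1)))$tier, "none")
  fs <- filter_size(mk(c(2, 4)))
  expect_equal(fs$n_ge_min, 1L)
  expect_equal(fs$calls$size_pass, c(FALSE, TRUE))
})

test_that("callset summaries compute length statistics and sex enrichment", {
  calls <- data.table::data.table(sample_id = c("a", "a", "b"),
                                  length_bp = c(1e6, 2e6, 100e6), state = "DEL")
  s <- summarize_callset(calls)
  expect_equal(s$median_length_bp, 2e6)
  expect_equal(s$mean_length_bp, 34.3333333e6, tolerance = 1e-7)
  expect_equal(s$n_events, 3L)
  expect_equal(s$n_samples, 2L)

  one <- summarize_callset(calls[3])
  expect_equal(one$median_length_bp, one$mean_length_bp)

  # null 2x2 table gives Fisher p = 1
  sex <- c(a = "M", b = "M", setNames(rep(c("M", "F"), c(8, 10)), paste0("x", 1:18)))
  # construct a balanced table: 10 male / 10 female, 2 mosaic samples both male
  sex20 <- setNames(rep(c("M", "F"), each = 10), c(paste0("m", 1:10), paste0("f", 1:10)))
  calls_bal <- data.table::data.table(
    sample_id = c(paste0("m", 1:5), paste0("f", 1:5)), length_bp = 5e6, state = "DEL")
  sb <- summarize_callset(calls_bal, sex = sex20)
  expect_equal(unname(sb$sex_table), matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(sb$fisher_p, 1.0)
  expect_equal(sb$pct_male_events, 50)
})
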