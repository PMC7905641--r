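test_that("column resolution handles standard, minimal and override headers", {
  idx <- resolve_columns("SNP Name\tChr\tPosition\tB Allele Freq\tLog R Ratio")
  expect_equal(idx[c("snp_id", "chrom", "pos", "baf", "lrr")],
               c(snp_id = 1L, chrom = 2L, pos = 3L, baf = 4L, lrr = 5L))

  idx2 <- resolve_columns("Name\tBAF\tLRR")
  expect_equal(idx2, c(snp_id = 1L, baf = 2L, lrr = 3L))
  expect_false(any(c("chrom", "pos") %in% names(idx2)))

  # per-sample prefixed GenomeStudio columns match by suffix
  idx3 <- resolve_columns("SNP Name\tS1.B Allele Freq\tS1.Log R Ratio")
  expect_equal(unname(idx3[c("baf", "lrr")]), c(2L, 3L))

  # custom synonym via config
  idx4 <- resolve_columns("probe\tbfreq\tLRR",
                          synonyms = list(snp_id = "probe", baf = "bfreq"))
  expect_equal(unname(idx4[c("snp_id", "baf", "lrr")]), 1:3)
})

test_that("column resolution fails loudly on missing or ambiguous columns", {
  expect_error(resolve_columns("SNP Name\tChr\tPosition\tB Allele Freq"),
               "Log R Ratio")
  expect_error(resolve_columns("Name\tBAF\tBAF\tLRR"), "multiple")
  expect_error(resolve_columns(""), "empty")
})

write_fixture <- function(lines, eol = "\n") {
  f <- tempfile(fileext = ".txt")
  con <- file(f, "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  f
}

fixture_lines <- c(
  "SNP Name\tChr\tPosition\tB Allele Freq\tLog R Ratio",
  "rs1\t1\t100\t0.50\t0.01",
  "rs2\t1\tREMOVE\t0.49\t0.02",
  "rs3\t1\t0\t0.51\t-0.01",
  "rs4\t1\t500\t0.02\t0.00",
  "rs5\t2\t900\t0.97\t0.05")

test_that("sanitization drops marked, zero-position and out-of-range records with counters", {
  f <- write_fixture(fixture_lines)
  tr <- parse_signal_file(f)
  expect_equal(nrow(tr$probes), 3L)
  expect_equal(tr$drop_counts[["removed_marker"]], 1L)
  expect_equal(tr$drop_counts[["pos_zero"]], 1L)
  expect_equal(tr$n_input, 5L)
  # counters sum: retained + dropped = input lines
  expect_equal(nrow(tr$probes) + sum(tr$drop_counts), tr$n_input)

  # out-of-range BAF dropped and counted
  f2 <- write_fixture(c(fixture_lines, "rs6\t2\t950\t1.2\t0.01"))
  tr2 <- parse_signal_file(f2)
  expect_equal(nrow(tr2$probes), 3L)
  expect_equal(tr2$drop_counts[["bad_baf"]], 1L)

  # non-finite LRR dropped, not imputed
  f3 <- write_fixture(c(fixture_lines, "rs7\t2\t980\t0.5\tNaN"))
  tr3 <- parse_signal_file(f3)
  expect_equal(tr3$drop_counts[["bad_lrr"]], 1L)

  # unrecognized contigs dropped
  f4 <- write_fixture(c(fixture_lines, "rs8\tMT\t100\t0.5\t0.0"))
  tr4 <- parse_signal_file(f4)
  expect_equal(tr4$drop_counts[["unknown_chrom"]], 1L)
  expect_equal(nrow(tr4$probes) + sum(tr4$drop_counts), tr4$n_input)
})

test_that("Windows line endings give a track identical to the Unix version", {
  f_lf <- write_fixture(fixture_lines, eol = "\n")
  f_crlf <- write_fixture(fixture_lines, eol = "\r\n")
  tr_lf <- parse_signal_file(f_lf, sample_id = "s")
  tr_crlf <- parse_signal_file(f_crlf, sample_id = "s")
  expect_identical(tr_lf$probes, tr_crlf$probes)
  expect_identical(tr_lf$drop_counts, tr_crlf$drop_counts)
})

test_that("map-file inputs supply coordinates and count unmapped probes", {
  f <- write_fixture(c("Name\tBAF\tLRR",
                       "rs1\t0.5\t0.0", "rs2\t0.4\t0.1", "rsX\t0.5\t0.0"))
  mapf <- write_fixture(c("SNP Name\tChr\tPosition",
                          "rs1\t1\t100", "rs2\t2\t200"))
  pm <- read_probe_map(mapf)
  tr <- parse_signal_file(f, probe_map = pm)
  expect_equal(nrow(tr$probes), 2L)
  expect_equal(tr$drop_counts[["unmapped"]], 1L)
  expect_equal(as.character(tr$probes$chrom), c("1", "2"))
  # without coordinates and without a map the parse is a hard error
  expect_error(parse_signal_file(f), "probe map")
})

test_that("sorting detects pre-sorted input, orders reversed input and breaks ties by probe id", {
  srt <- make_track("1", c(10, 20, 30), c(0.5, 0.5, 0.5), c(0, 0, 0), sorted = FALSE)
  s1 <- ensure_sorted(srt)
  expect_true(s1$presorted)
  expect_identical(s1$probes, srt$probes)
  # idempotent
  expect_identical(ensure_sorted(s1), s1)

  rev <- make_track("1", c(30, 20, 10), c(0.1, 0.2, 0.3), c(0, 0, 0), sorted = FALSE)
  s2 <- ensure_sorted(rev)
  expect_false(s2$presorted)
  expect_equal(s2$probes$pos, c(10L, 20L, 30L))

  tie <- make_track(c("1", "1"), c(50, 50), c(0.5, 0.6), c(0, 0),
                    snp_id = c("zzz", "aaa"), sorted = FALSE)
  s3 <- ensure_sorted(tie)
  expect_equal(s3$probes$snp_id, c("aaa", "zzz"))
})

test_that("a written signal file parses back to the same records", {
  set.seed(11)
  tr <- make_track(sample(c("1", "2", "X"), 50, replace = TRUE),
                   sample.int(5e6, 50), round(runif(50), 4),
                   round(rnorm(50, 0, 0.2), 4), sample_id = "rt")
  f <- tempfile(fileext = ".txt")
  write_signal_file(tr, f)
  back <- parse_signal_file(f, sample_id = "rt")
  expect_identical(back$probes, tr$probes)
})

test_that("call export uses BED half-open and TSV 1-based conventions", {
  calls <- data.table::data.table(
    sample_id = "s1", chrom = factor("2", levels = c(as.character(1:22), "X", "Y")),
    start_bp = 100000001L, end_bp = 110000000L, length_bp = 10000000L,
    state = "DEL", n_windows = 10L, n_dev_probes = 500L,
    clearing_ratio_min = 2.5, bdev = 0.1, cell_fraction = 0.33)
  fb <- tempfile(fileext = ".bed")
  write_calls(calls, fb, format = "bed")
  lines <- readLines(fb)
  expect_match(lines[2], "^2\t100000000\t110000000\t")

  ft <- tempfile(fileext = ".tsv")
  write_calls(calls, ft, format = "tsv")
  tsv <- data.table::fread(ft)
  expect_equal(tsv$start_bp, 100000001L)
  expect_equal(tsv$end_bp, 110000000L)

  # empty callset writes a header-only file
  fe <- tempfile(fileext = ".bed")
  write_calls(calls[0], fe, format = "bed")
  expect_equal(length(readLines(fe)), 1L)

  # two calls come out in genome order
  two <- data.table::rbindlist(list(calls, data.table::copy(calls)[
    , `:=`(chrom = factor("1", levels = levels(calls$chrom)), start_bp = 5L,
           end_bp = 4000005L)]))
  f2 <- tempfile(fileext = ".tsv")
  write_calls(two, f2)
  out <- data.table::fread(f2)
  expect_equal(as.character(out$chrom), c("1", "2"))
})
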