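library(data.table)

# Build a sorted signal track from parallel vectors.
make_track <- function(chrom, pos, baf, lrr, sample_id = "fix",
                       snp_id = NULL, sorted = TRUE) {
  n <- length(pos)
  probes <- data.table(
    snp_id = snp_id %||% sprintf("p%05d", seq_len(n)),
    chrom = factor(as.character(chrom), levels = c(as.character(1:22), "X", "Y")),
    pos = as.integer(pos),
    baf = as.numeric(baf), lrr = as.numeric(lrr))
  tr <- structure(list(sample_id = sample_id, probes = probes, sorted = FALSE,
                       presorted = NA, n_input = n,
                       drop_counts = integer()),
                  class = "signal_track")
  if (sorted) ensure_sorted(tr) else tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small-genome simulation parameters for fast unit tests.
small_params <- function(seed, ...) {
  sim_params(n_chroms = 3L, chrom_length_bp = 30e6, probes_per_mb = 200,
             seed = seed, ...)
}

# Independent per-probe bucketing oracle for window tallies: a plain loop
# that never touches the scan implementation.
oracle_windows <- function(track, window_bp = 1e6) {
  p <- track$probes
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(p))) {
    tile <- (p$pos[i] - 1) %/% window_bp
    key <- paste(as.character(p$chrom[i]), tile, sep = "|")
    cur <- get0(key, envir = acc,
                ifnotfound = list(n = 0L, ab = 0L, lo = 0L, hi = 0L, hom = 0L,
                                  lrr = numeric(), het_baf = numeric()))
    b <- p$baf[i]
    if (b >= 0.4 && b < 0.6) cur$ab <- cur$ab + 1L
    else if (b >= 0.1 && b < 0.4) cur$lo <- cur$lo + 1L
    else if (b >= 0.6 && b < 0.9) cur$hi <- cur$hi + 1L
    else cur$hom <- cur$hom + 1L
    cur$n <- cur$n + 1L
    cur$lrr <- c(cur$lrr, p$lrr[i])
    if (b > 0.1 && b < 0.9) cur$het_baf <- c(cur$het_baf, b)
    assign(key, cur, envir = acc)
  }
  keys <- ls(acc)
  rbindlist(lapply(keys, function(key) {
    cur <- get(key, envir = acc)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sdv <- if (length(cur$het_baf) >= 2) {
      m <- sum(cur$het_baf) / length(cur$het_baf)
      sqrt(sum((cur$het_baf - m)^2) / length(cur$het_baf))
    } else NA_real_
    data.table(chrom = parts[1], tile = as.integer(parts[2]),
               n_probes = cur$n, n_ab = cur$ab, n_ab_low = cur$lo,
               n_ab_high = cur$hi, n_hom = cur$hom,
               avg_lrr = mean(cur$lrr), baf_sd_het = sdv)
  }))
}

# Independent linear-interpolation quartile oracle (h = (n-1)p + 1).
oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Minimal genome_windows wrapper around a hand-built window table.
fake_gw <- function(windows, sample_id = "fake", genome_avg_lrr = 0,
                    genome_baf_sd = 0.04) {
  structure(list(sample_id = sample_id, windows = as.data.table(windows),
                 window_bp = 1e6L, genome_avg_lrr = genome_avg_lrr,
                 genome_baf_sd = genome_baf_sd,
                 genome_het_ab_frac = 0.3,
                 n_probes = sum(windows$n_probes)),
            class = "genome_windows")
}

# Window rows with sane defaults; override per test.
fake_windows <- function(n, chrom = "1", baf_sd = 0.04, lrr = 0,
                         n_probes = 200L, n_ab = 60L, n_lo = 1L, n_hi = 1L) {
  data.table(chrom = factor(rep(chrom, length.out = n),
                            levels = c(as.character(1:22), "X", "Y")),
             window_start = seq(1L, by = 1000000L, length.out = n),
             window_end = seq(1000000L, by = 1000000L, length.out = n),
             n_ab = rep(n_ab, length.out = n),
             n_ab_low = rep(n_lo, length.out = n),
             n_ab_high = rep(n_hi, length.out = n),
             n_hom = pmax(rep(n_probes, length.out = n) - n_ab - n_lo - n_hi, 0L),
             n_probes = rep(as.integer(n_probes), length.out = n),
             avg_lrr = rep(lrr, length.out = n),
             baf_sd_het = rep(baf_sd, length.out = n),
             first_dev_pos = NA_integer_, last_dev_pos = NA_integer_,
             terminal = FALSE)
}

# Random small track for property tests.
random_track <- function(seed, n = 300L, n_chrom = 3L, span = 5e6) {
  set.seed(seed)
  make_track(chrom = sample(as.character(seq_len(n_chrom)), n, replace = TRUE),
             pos = sample.int(span, n, replace = TRUE),
             baf = runif(n), lrr = rnorm(n, 0, 0.2),
             sample_id = paste0("rnd", seed))
}
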