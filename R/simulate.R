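# Synthetic BAF/LRR signal generation with known injected mosaic events.
#
# The generator reproduces the banding structure of SNP-array signal: tight
# homozygous clouds at BAF 0 and 1, a heterozygous cloud at 0.5, and -- inside
# a mosaic event -- the het cloud split into two bands displaced symmetrically
# about 0.5, with an LRR shift whose magnitude depends on the copy state and
# cell fraction.

# Approximate human autosome lengths (Mb), used as the default genome model.
# At the default 200 probes/Mb this yields ~575k probes, i.e. a 610k-class
# array after QC.
.autosome_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                  115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Simulation parameters
#'
#' Defaults emulate a 610k-density genotyping array on a clean sample:
#' 200 probes/Mb over 22 autosomes of roughly human lengths, one third of
#' probes heterozygous, Gaussian BAF noise with sd 0.04 (truncated to
#' `[0, 1]`) and Gaussian LRR noise with sd 0.15.
#'
#' @param n_chroms number of chromosomes (default 22).
#' @param chrom_length_bp chromosome lengths in bp; default approximate
#'   human autosome lengths (recycled/truncated to `n_chroms`).
#' @param probes_per_mb probe density (default 200).
#' @param het_fraction probability a probe is heterozygous (default 0.33).
#' @param baf_noise_sd Gaussian sd of BAF noise on heterozygous probes,
#'   truncated to `[0,1]` (default 0.04).
#' @param hom_baf_noise_sd Gaussian sd of BAF noise on homozygous probes
#'   (default 0.02): homozygous clusters are much tighter than the het
#'   cloud on real arrays, and at this sd a hom probe strays into
#'   (0.1, 0.9) with probability below 1e-4.
#' @param lrr_noise_sd Gaussian sd of LRR noise (default 0.15).
#' @param cn0_baf_sd BAF spread around 0/1 inside a simulated homozygous
#'   (copy-number 0) deletion, where BAF is intensity noise (default 0.15).
#' @param cn0_lrr mean LRR inside a simulated CN0 region (default -3.5).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_chroms = 22L, chrom_length_bp = NULL,
                       probes_per_mb = 200, het_fraction = 0.33,
                       baf_noise_sd = 0.04, hom_baf_noise_sd = 0.02,
                       lrr_noise_sd = 0.15,
                       cn0_baf_sd = 0.15, cn0_lrr = -3.5, seed = NULL) {
  if (is.null(chrom_length_bp))
    chrom_length_bp <- .autosome_mb[seq_len(min(n_chroms, 22L))] * 1e6
  chrom_length_bp <- rep_len(chrom_length_bp, n_chroms)
  stopifnot(n_chroms >= 1L, all(chrom_length_bp > 0), probes_per_mb > 0,
            het_fraction > 0, het_fraction < 1,
            baf_noise_sd > 0, hom_baf_noise_sd > 0, lrr_noise_sd > 0)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length_bp = chrom_length_bp,
                 probes_per_mb = probes_per_mb,
                 het_fraction = het_fraction,
                 baf_noise_sd = baf_noise_sd,
                 hom_baf_noise_sd = hom_baf_noise_sd,
                 lrr_noise_sd = lrr_noise_sd,
                 cn0_baf_sd = cn0_baf_sd,
                 cn0_lrr = cn0_lrr,
                 seed = seed),
            class = "sim_params")
}

#' Construct a table of ground-truth mosaic events
#'
#' @param chrom,start_bp,end_bp event coordinates (1-based inclusive).
#' @param state one of `"DEL"`, `"DUP"`, `"CNLOH"`, or `"CN0"` (a full
#'   homozygous deletion, used to exercise the homozygous-deletion filter).
#' @param fraction cell fraction in `(0, 1]`; ignored for `CN0`.
#' @return `data.table` of events, validated non-overlapping.
#' @export
truth_events <- function(chrom, start_bp, end_bp, state, fraction = 1) {
  ev <- data.table::data.table(chrom = as.character(chrom),
                               start_bp = as.numeric(start_bp),
                               end_bp = as.numeric(end_bp),
                               state = as.character(state),
                               fraction = as.numeric(fraction))
  stopifnot(all(ev$start_bp < ev$end_bp),
            all(ev$fraction > 0 & ev$fraction <= 1),
            all(ev$state %in% c("DEL", "DUP", "CNLOH", "CN0")))
  data.table::setorder(ev, chrom, start_bp)
  if (nrow(ev) > 1L) {
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start_bp[-1] <= ev$end_bp[-nrow(ev)]))
      stop("truth events must not overlap")
  }
  ev[]
}

#' Expected heterozygous BAF band centres under a mosaic event
#'
#' Standard allelic mixture arithmetic: with a cell fraction `f`, a
#' heterozygous locus has B-allele copy ratio
#' * deletion: `(1-f)/(2-f)` or `1/(2-f)` (A or B allele lost),
#' * duplication: `1/(2+f)` or `(1+f)/(2+f)` (A or B allele gained),
#' * copy-neutral LOH: `(1-f)/2` or `(1+f)/2`.
#' Bands are symmetric about 0.5, collapse to 0.5 at `f = 0`, and at `f = 1`
#' reach the constitutional limits (loss: 0/1; trisomy: 1/3, 2/3).
#'
#' @param state `"DEL"`, `"DUP"` or `"CNLOH"`.
#' @param f cell fraction in `[0, 1]`.
#' @return numeric length-2 vector `(lower, upper)` of band centres.
#' @export
expected_baf_bands <- function(state, f) {
  stopifnot(f >= 0, f <= 1)
  switch(state,
         DEL = c((1 - f) / (2 - f), 1 / (2 - f)),
         DUP = c(1 / (2 + f), (1 + f) / (2 + f)),
         CNLOH = c((1 - f) / 2, (1 + f) / 2),
         stop(sprintf("unknown state '%s'", state)))
}

#' Expected mean LRR shift under a mosaic event
#'
#' Copy-ratio model: average copy number `2 - f` (deletion) or `2 + f`
#' (duplication) gives an LRR shift of `log2((2 -/+ f)/2)`; copy-neutral LOH
#' shifts nothing. The gain for a duplication is smaller in magnitude than
#' the loss for a deletion at every `f`, which is why mosaic duplications
#' are harder to detect from intensity.
#'
#' @inheritParams expected_baf_bands
#' @return expected LRR shift (log2 scale).
#' @export
expected_lrr_shift <- function(state, f) {
  stopifnot(f >= 0, f <= 1)
  switch(state,
         DEL = log2((2 - f) / 2),
         DUP = log2((2 + f) / 2),
         CNLOH = 0,
         stop(sprintf("unknown state '%s'", state)))
}

#' B-deviation as a function of cell fraction
#'
#' Displacement of the lower het band from 0.5: `f/(2(2-f))` for deletion,
#' `f/(2(2+f))` for duplication, `f/2` for CNLOH. Strictly increasing in `f`
#' for each state, and ordered CNLOH > DEL > DUP at matched `f` (duplications
#' deviate least, hence are hardest to detect).
#'
#' @inheritParams expected_baf_bands
#' @return B-deviation in `[0, 0.5]`.
#' @export
expected_bdev <- function(state, f) {
  0.5 - expected_baf_bands(state, f)[1]
}

#' Simulate one sample's signal track with injected mosaic events
#'
#' Probes are placed uniformly at the stated density and sorted. Outside
#' events, heterozygous probes draw BAF from a truncated
#' `Normal(0.5, baf_noise_sd)` and homozygous probes from truncated normals
#' at 0 or 1; LRR is `Normal(0, lrr_noise_sd)`. Inside a DEL/DUP/CNLOH
#' event at cell fraction `f`, heterozygous probes split equally
#' (Bernoulli 1/2 per probe: A- or B-allele affected) between the two
#' expected band centres with the same noise, and LRR is shifted by the
#' expected amount. Inside a `CN0` event, genotype structure disappears:
#' BAF is edge noise around 0/1 (`cn0_baf_sd`) and LRR drops to `cn0_lrr`.
#' BAF noise is clipped (not resampled) at the `[0, 1]` edges, slightly
#' inflating mass at 0/1 as real arrays do. Fully reproducible from
#' `params$seed`.
#'
#' @param params a `sim_params` object.
#' @param events optional `data.table` from [truth_events()].
#' @param sample_id sample label (default `"sim"`).
#' @return list with `track` (a sorted `signal_track`) and `truth` (the
#'   event table).
#' @export
simulate_sample <- function(params, events = NULL, sample_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(events)) events <- truth_events(character(), numeric(),
                                              numeric(), character())[0]

  chroms <- as.character(seq_len(params$n_chroms))
  per_chrom <- vector("list", params$n_chroms)
  for (ci in seq_len(params$n_chroms)) {
    len <- params$chrom_length_bp[ci]
    n <- max(1L, round(params$probes_per_mb * len / 1e6))
    pos <- sort.int(ceiling(stats::runif(n) * len))
    het <- stats::runif(n) < params$het_fraction
    hom_b <- stats::runif(n) < 0.5  # BB vs AA for homozygous probes
    baf <- ifelse(het, 0.5, ifelse(hom_b, 1, 0)) +
      stats::rnorm(n, 0, ifelse(het, params$baf_noise_sd,
                                params$hom_baf_noise_sd))
    lrr <- stats::rnorm(n, 0, params$lrr_noise_sd)

    ev_c <- events[events$chrom == chroms[ci], ]
    if (nrow(ev_c)) {
      for (k in seq_len(nrow(ev_c))) {
        inside <- pos >= ev_c$start_bp[k] & pos <= ev_c$end_bp[k]
        if (!any(inside)) next
        if (ev_c$state[k] == "CN0") {
          n_in <- sum(inside)
          mode <- ifelse(stats::runif(n_in) < 0.5, 1, 0)
          baf[inside] <- mode + stats::rnorm(n_in, 0, params$cn0_baf_sd)
          lrr[inside] <- params$cn0_lrr + stats::rnorm(n_in, 0, params$lrr_noise_sd)
        } else {
          bands <- expected_baf_bands(ev_c$state[k], ev_c$fraction[k])
          hit <- inside & het
          n_hit <- sum(hit)
          if (n_hit) {
            upper <- stats::runif(n_hit) < 0.5
            centre <- ifelse(upper, bands[2], bands[1])
            baf[hit] <- centre + stats::rnorm(n_hit, 0, params$baf_noise_sd)
          }
          lrr[inside] <- lrr[inside] + expected_lrr_shift(ev_c$state[k],
                                                          ev_c$fraction[k])
        }
      }
    }
    baf <- pmin(pmax(baf, 0), 1)
    per_chrom[[ci]] <- data.table::data.table(
      snp_id = sprintf("snp_%s_%07d", chroms[ci], seq_len(n)),
      chrom = chroms[ci], pos = as.integer(pos), baf = baf, lrr = lrr)
  }
  probes <- data.table::rbindlist(per_chrom)
  probes[, chrom := chrom_factor(chrom)]
  track <- new_signal_track(probes, sample_id, sorted = FALSE)
  track <- ensure_sorted(track)
  list(track = track, truth = events)
}

#' Write a truth-event table as BED
#'
#' @param truth `data.table` from [truth_events()].
#' @param path output path (0-based half-open BED).
#' @export
write_truth_bed <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tstate\tfraction", con)
  if (nrow(truth) > 0) {
    bed <- truth[, .(chrom, start = format(start_bp - 1, scientific = FALSE, trim = TRUE),
                     end = format(end_bp, scientific = FALSE, trim = TRUE),
                     state, fraction)]
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
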