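---
title: "Windowed allelic-imbalance detection of mosaic CNVs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed allelic-imbalance detection of mosaic CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
library(data.table)
```

## The signal model

A SNP array reports, per probe, a B-allele frequency (BAF: the normalized
fraction of signal from the B allele) and a log R ratio (LRR: log2 total
intensity relative to a diploid reference). In a diploid genome,
heterozygous probes cluster at BAF 0.5 and homozygous probes at 0 and 1;
LRR is centred at 0.

Mosaicism is a mixture: a fraction $f$ of cells carries a copy-number event
while $1-f$ are diploid. At a heterozygous locus the aggregate B-allele
copy ratio is an average over the mixture, so the 0.5 band splits into two
bands symmetric about 0.5. Counting allele copies gives the band centres

* deletion: $\frac{1-f}{2-f}$ and $\frac{1}{2-f}$ (average copy number $2-f$),
* duplication: $\frac{1}{2+f}$ and $\frac{1+f}{2+f}$ (average copy number $2+f$),
* copy-neutral LOH: $\frac{1-f}{2}$ and $\frac{1+f}{2}$ (copy number 2).

The displacement of the lower band from 0.5 (the B-deviation) is
$f/(2(2-f))$, $f/(2(2+f))$ and $f/2$ respectively — strictly increasing in
$f$, and ordered CNLOH > DEL > DUP at matched $f$ (they coincide only in the
degenerate limits $f=0$, and DEL = CNLOH at $f=1$). The expected LRR shift
is $\log_2\frac{2-f}{2}$ (DEL), $\log_2\frac{2+f}{2}$ (DUP) and 0 (CNLOH);
the duplication gain is smaller in magnitude than the deletion loss at every
$f$, which is the quantitative reason mosaic duplications are the harder
detection problem. These functions are exposed as `expected_baf_bands()`,
`expected_lrr_shift()` and `expected_bdev()`, and `estimate_cell_fraction()`
inverts them to annotate calls with an implied cell fraction.

## The detection procedure

Detection is per sample and fully independent across samples.

**Windowing.** After sorting by chromosome (canonical order 1–22, X, Y) and
position, probes are tallied in fixed, non-overlapping genomic tiles of
`window_bp` = 1 Mb. Fixed tiles (rather than probe-count windows) make
windows comparable across samples and platforms. Per window we record the
probe counts in the five BAF bands (0–0.1), (0.1–0.4), (0.4–0.6),
(0.6–0.9), (0.9–1), the mean LRR, and the population standard deviation of
BAF restricted to the open interval (0.1, 0.9) — the statistic that grows
when the AB band splits.

**Per-sample IQR thresholds.** Window BAF SD and window mean LRR are
summarized by quartiles over that sample's eligible windows. A window is a
candidate when its BAF SD strictly exceeds $q_3 + 1.5\,\mathrm{IQR}$ *and*
it contains at least one probe in the deviating ranges
(0.1–0.4) ∪ (0.6–0.9); mean LRR below $q_1 - 1.5\,\mathrm{IQR}$ labels it
a deletion, above $q_3 + 1.5\,\mathrm{IQR}$ a duplication, and in between
copy-neutral LOH. Deriving thresholds from the sample's own genome rather
than a cohort keeps the scan single-pass and batch-free, at the cost that
the boxplot rule always flags a small tail (about 0.5–0.7% of ~2,900
genome-wide windows) of single-window noise candidates; these are cheap to
carry and are removed by the size filter downstream.

**Merging and refinement.** Runs of adjacent same-state candidate windows
collapse into one event; two same-state events merge when the intervening
gap is at most `gap_fraction` (default 0.2) of the combined span, iterated
to a fixpoint — the fragment-cleaning semantics familiar from CNV
post-processing tools. Events never merge across states or chromosomes.
Tile-aligned spans are then refined to the first and last probe with BAF in
the deviating ranges, which is what the reported breakpoints mean.

**Filtering.** A true homozygous deletion (copy number 0) has no genotype:
its BAF is intensity noise, which the window statistic happily mistakes for
band splitting. With an external CN0 callset, any refined call overlapping
an interval by ≥ 1 bp is removed (no reciprocal-overlap fraction is
imposed). Without one, an approximation subroutine removes calls whose span
shows the CN0 signature: mean LRR < −2.0 — far beyond the −1 limit of any
mosaic (or even constitutional hemizygous) deletion — together with an
AB-band (0.4–0.6) probe density below 10% of the sample's genome-wide AB
density. Both cutoffs are operational parameters of this package, exposed
in `run_config()` and recorded in the filter log. Finally, calls at or
above `min_len_bp` = 3 Mb form the high-confidence stratum, and the sample
is tiered by whether it has none, several, or exactly one qualifying call —
the last being the highest-specificity situation for downstream curation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_bp` | 1,000,000 | bp | resolves multi-Mb events at array densities (~200 probes/window) |
| `min_probes_per_window` | 20 | probes | prevents SD estimates on near-empty windows |
| `gap_fraction` | 0.2 | — | fragment-merge tolerance; 1 Mb gap closes between 4-Mb flanks, 3 Mb does not |
| `min_len_bp` | 3,000,000 | bp | high-confidence size stratum |
| `qc_baf_sd_max` | 0.20 | BAF SD | clean samples sit near the het noise sd (~0.04); uniform BAF noise gives ~0.23 |
| `clearing_ratio_min` | 2 | — | curation annotation threshold (see below) |
| `homdel_lrr_max` | −2.0 | LRR | CN0 signature; mosaic shifts cannot exceed −1 |
| `homdel_het_density_frac` | 0.10 | — | AB-density collapse relative to genome-wide |
| `max_raw_events` | 50 | events | noisy-sample guard, ~3× the null expectation of IQR-outlier windows |
| `exclude_chroms` | X, Y | — | single-copy chromosomes in males have no AB band and would corrupt quartiles |

Two parameter choices deserve their reasoning spelled out:

* **The clearing ratio is an annotation, not a removal filter.** The AB
  clearing ratio of a window — deviating-het observations divided by
  proper-AB observations — discriminates sharply *validated* calls, and a
  value of 2 (e.g. 16 + 16 deviating vs 15 proper-AB probes in one window)
  characterizes high-fraction events. But at $f = 0.3$ a deletion's bands
  sit at 0.41/0.59, mostly inside the (0.4–0.6) AB bin, giving ratios near
  0.6; removing calls below 2 would delete every low-fraction true event.
  Calls therefore carry `clearing_ratio_min` (the minimum over their merged
  windows) and a boolean `curated` flag at the threshold, leaving the
  cutoff to post-hoc curation, where it belongs.
* **`max_raw_events` = 50.** The IQR boxplot rule flags ~0.5–0.7% of
  windows on a clean genome — 15–20 single-window candidates over ~2,900
  windows is the *expected null outcome*, not a pathology. A guard at 20
  would suppress typical clean samples; 50 sits ~3× above the null mean
  and still catches genuinely noise-dominated genomes.

## Numerical choices

* **Quartiles** are linear-interpolation quartiles between order statistics
  (`stats::quantile` type 7), centralized in one internal helper so the
  definition is swappable package-wide.
* **BAF bins** are half-open $[lo, hi)$ with 1.0 closed into the top bin.
  The band boundaries carry no probability mass under noisy signal, so any
  consistent closure gives identical results away from exact boundary
  values.
* **Population SD** (denominator $n$) is used for the window BAF SD; at
  ~60 het probes per window the difference from the $n-1$ form is far below
  the threshold resolution.
* **Ties at thresholds** are conservative: a window exactly at a threshold
  stays NORMAL.
* **Tie-breaking in sorting** is deterministic by probe id at identical
  (chromosome, position).
* **Degenerate inputs**: fewer than 4 eligible windows is a hard error
  (quartiles undefined in any useful sense); a window with < 2 het probes
  has no BAF SD and is ineligible; samples with no het probes at all fail
  QC as indeterminate.

## What the simulator emulates — and what it does not

`simulate_sample()` generates the genotype-band structure of array signal:
probes placed uniformly at 200 probes/Mb over 22 chromosomes of
approximately human autosome lengths (~575k probes, a 610k-class array),
heterozygous with probability 0.33, BAF noise Gaussian and clipped to
$[0,1]$ (clipping slightly inflates mass at 0/1, as real arrays show), LRR
noise Gaussian with sd 0.15. Het noise sd defaults to 0.04; homozygous
clusters are far tighter on real arrays, and their noise defaults to 0.02,
at which a hom probe strays into (0.1, 0.9) with probability below
$10^{-4}$. This separation matters: at a shared sd of 0.04, hom-cloud
leakage (~0.8 probes per window at BAF ≈ 0.1) inflates the window BAF-SD
quartiles enough to push the outlier threshold onto the signal of a 30%
deletion, fragmenting true events — a failure mode of the *generator*, not
the detector. Inside an event, het probes split equally (Bernoulli 1/2 per
probe — the A- and B-allele forms are equally likely) between the two model
band centres; a `CN0` event state replaces genotype structure with edge
noise (sd 0.15 around 0/1) and LRR −3.5, to exercise the
homozygous-deletion filter.

Not emulated: GC waves and other LRR autocorrelation, batch and plate
effects, probe-specific bias, population LD structure, sex chromosomes, and
cellularity gradients along chromosomes. Passing recovery tests on this
generator therefore demonstrates the algorithm's correctness under its own
signal model — clean banding plus white noise — not its performance on any
particular real cohort, where wave artefacts and probe quality dominate the
false-positive budget.

## Problem sizes used by the test suite

Unit tests run on 3-chromosome, 30-Mb mini-genomes (18k probes) for speed;
the end-to-end recovery study uses 100 full 610k-density samples with one
10-Mb deletion at $f = 0.3$ plus 100 clean samples, the scale at which the
recovery and false-call rates are stable to a few percent. The windowing
and quartile engines are additionally cross-checked against brute-force
per-probe oracles on 1,000 random small tracks.

## Known limitations

* CNN-LOH is classified by exclusion (high BAF SD, LRR inside both
  thresholds); no explicit LRR-flatness test is made, so a low-fraction
  duplication with an LRR shift under the threshold resolution will be
  labelled CNLOH.
* The cell-fraction estimate inverts the band model at the median absolute
  het deviation; it is a moment estimate, biased upward at small $f$ where
  noise dominates the displacement, and should be read as indicative.
* Events below ~2 Mb are structurally invisible at the default window size;
  shrink `window_bp` (and expect noisier window SDs) to target smaller
  events.
* Sample-level concordance treats a sample as one unit; two callers
  agreeing on a sample need not agree on the event's locus. Interval-level
  comparison is possible by exporting calls as BED and intersecting
  externally.
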