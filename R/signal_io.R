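# Reading, sanitizing and writing per-sample BAF/LRR signal files.

# Default column-name synonyms, matched case-insensitively after collapsing
# spaces, dots, dashes and underscores. Covers Illumina GenomeStudio / iaap
# and Affymetrix Genotyping Workbench / apt text exports.
.col_synonyms <- list(
  snp_id = c("snp name", "name", "snp", "snp id", "marker", "probe set id",
             "probeset id"),
  chrom  = c("chr", "chromosome", "chrom"),
  pos    = c("position", "pos", "mapinfo", "physical position", "bp"),
  baf    = c("b allele freq", "baf", "b allele frequency", "ballelefreq"),
  lrr    = c("log r ratio", "lrr", "logrratio", "log2 ratio")
)

.norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ ._-]+", " ", x)
  trimws(x)
}

#' Resolve signal-file columns from a header line
#'
#' Signal exports differ in column order and naming between platforms, so the
#' header is assessed dynamically. The minimum required set is the probe
#' identifier, BAF and LRR; chromosome and position may instead come from a
#' separate probe map (see [read_probe_map()]).
#'
#' @param header character vector of column names, or a single tab-delimited
#'   header line.
#' @param synonyms optional named list extending the built-in synonym table;
#'   entries are appended to the defaults for fields
#'   `snp_id`, `chrom`, `pos`, `baf`, `lrr`.
#' @return named integer vector of column indices for the fields found;
#'   always contains `snp_id`, `baf` and `lrr`, and `chrom`/`pos` when
#'   present in the header.
#' @examples
#' resolve_columns("SNP Name\tChr\tPosition\tB Allele Freq\tLog R Ratio")
#' @export
resolve_columns <- function(header, synonyms = NULL) {
  if (length(header) == 1L && grepl("\t", header)) {
    header <- strsplit(header, "\t", fixed = TRUE)[[1]]
  }
  if (length(header) == 0L || all(!nzchar(header)))
    stop("empty header line", call. = FALSE)
  syn <- .col_synonyms
  for (f in names(synonyms)) syn[[f]] <- unique(c(syn[[f]], tolower(synonyms[[f]])))
  hn <- .norm_header(header)

  find_field <- function(field) {
    hits <- which(hn %in% .norm_header(syn[[field]]))
    if (length(hits) == 0L) {
      # GenomeStudio full-table exports prefix per-sample columns with the
      # sample name ("Sample1.B Allele Freq"); accept a suffix match.
      pat <- paste0(" (", paste(.norm_header(syn[[field]]), collapse = "|"), ")$")
      hits <- grep(pat, hn)
    }
    if (length(hits) > 1L)
      stop(sprintf("column for '%s' matched multiple headers: %s",
                   field, paste(header[hits], collapse = ", ")), call. = FALSE)
    if (length(hits) == 1L) hits else NA_integer_
  }

  idx <- vapply(names(syn), find_field, integer(1))
  required <- c(snp_id = "SNP Name", baf = "B Allele Freq", lrr = "Log R Ratio")
  for (f in names(required)) {
    if (is.na(idx[[f]]))
      stop(sprintf("required column '%s' (%s) not found in header", required[[f]], f),
           call. = FALSE)
  }
  idx[!is.na(idx)]
}

#' Read a probe map file
#'
#' A probe map links probe identifiers to genomic coordinates for signal
#' files exported without chromosome/position columns (a common disk-space
#' optimization). Expected columns: probe id, chromosome, position
#' (tab-delimited, header optional, synonyms as in [resolve_columns()]).
#'
#' @param path path to a tab-delimited map file.
#' @return `data.table` with columns `snp_id`, `chrom`, `pos`, one row per
#'   probe id.
#' @export
read_probe_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character", showProgress = FALSE)
  if (ncol(dt) < 3L) stop("probe map needs at least 3 columns (id, chrom, pos)")
  idx <- tryCatch(
    resolve_columns(names(dt)),
    error = function(e) c(snp_id = 1L, chrom = 2L, pos = 3L)
  )
  if (is.na(idx["chrom"] %||% NA) || is.na(idx["pos"] %||% NA) ||
      !all(c("chrom", "pos") %in% names(idx)))
    idx <- c(snp_id = 1L, chrom = 2L, pos = 3L)
  out <- dt[, .(snp_id = .SD[[idx[["snp_id"]]]],
                chrom  = .SD[[idx[["chrom"]]]],
                pos    = suppressWarnings(as.numeric(.SD[[idx[["pos"]]]])))]
  out <- unique(out, by = "snp_id")
  out <- out[is.finite(pos) & pos >= 1]
  out[]
}

new_signal_track <- function(probes, sample_id, sorted = FALSE,
                             drop_counts = integer(), n_input = nrow(probes),
                             presorted = NA) {
  structure(list(sample_id = sample_id,
                 probes = probes,
                 sorted = sorted,
                 presorted = presorted,
                 n_input = n_input,
                 drop_counts = drop_counts),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> sample '%s': %d probes on %d chromosome(s)%s\n",
              x$sample_id, nrow(x$probes),
              length(unique(x$probes$chrom)),
              if (isTRUE(x$sorted)) ", sorted" else ""))
  if (sum(x$drop_counts) > 0) {
    d <- x$drop_counts[x$drop_counts > 0]
    cat("  dropped:", paste(sprintf("%s=%d", names(d), d), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse a per-sample signal file into a signal track
#'
#' Reads a tab-delimited BAF/LRR export, sanitizes it and returns an ordered
#' per-probe track. Both Unix and Windows line endings are accepted.
#' Sanitization drops, with per-reason counters:
#' * probes whose position carries the `REMOVE` marker (low call rate or
#'   failed liftover upstream),
#' * probes at position 0,
#' * probes with non-numeric or out-of-range BAF (outside `[0,1]`) or
#'   non-finite LRR,
#' * probes on unrecognized contigs (anything outside 1-22, X, Y),
#' * probes absent from the map when a map is required.
#'
#' @param path path to the signal file.
#' @param sample_id sample label; defaults to the file name without extension.
#' @param probe_map optional `data.table` from [read_probe_map()]; required
#'   when the file has no chromosome/position columns.
#' @param synonyms column-name overrides passed to [resolve_columns()].
#' @param sort sort the track after parsing (default `TRUE`).
#' @return a `signal_track`: list with `sample_id`, a `probes` `data.table`
#'   (`snp_id`, `chrom`, `pos`, `baf`, `lrr`), the sanitization counters in
#'   `drop_counts` and the raw input line count in `n_input`.
#' @export
parse_signal_file <- function(path, sample_id = NULL, probe_map = NULL,
                              synonyms = NULL, sort = TRUE) {
  if (!file.exists(path)) stop(sprintf("signal file not found: %s", path))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", showProgress = FALSE)
  idx <- resolve_columns(names(dt), synonyms = synonyms)
  has_coords <- all(c("chrom", "pos") %in% names(idx))
  if (!has_coords && is.null(probe_map))
    stop("signal file has no chromosome/position columns and no probe map was supplied")

  n_input <- nrow(dt)
  drops <- c(removed_marker = 0L, pos_zero = 0L, bad_pos = 0L, unmapped = 0L,
             unknown_chrom = 0L, bad_baf = 0L, bad_lrr = 0L)

  rec <- data.table::data.table(
    snp_id = dt[[idx[["snp_id"]]]],
    baf = suppressWarnings(as.numeric(dt[[idx[["baf"]]]])),
    lrr = suppressWarnings(as.numeric(dt[[idx[["lrr"]]]]))
  )
  if (has_coords) {
    pos_raw <- dt[[idx[["pos"]]]]
    rec[, chrom := dt[[idx[["chrom"]]]]]
    unmapped <- rep(FALSE, nrow(rec))
  } else {
    m <- probe_map[match(rec$snp_id, probe_map$snp_id)]
    pos_raw <- as.character(m$pos)
    rec[, chrom := m$chrom]
    unmapped <- is.na(m$pos)
    drops["unmapped"] <- sum(unmapped)
  }

  removed <- !unmapped & !is.na(pos_raw) & toupper(trimws(pos_raw)) == "REMOVE"
  drops["removed_marker"] <- sum(removed)
  pos <- suppressWarnings(as.numeric(pos_raw))
  bad_pos <- !unmapped & !removed & is.na(pos)
  drops["bad_pos"] <- sum(bad_pos)
  zero <- !removed & !bad_pos & !is.na(pos) & pos == 0
  drops["pos_zero"] <- sum(zero)
  rec[, pos := pos]

  keep <- !unmapped & !removed & !bad_pos & !zero
  rec <- rec[keep]

  rec[, chrom := normalize_chrom(chrom)]
  unk <- is.na(rec$chrom)
  drops["unknown_chrom"] <- sum(unk)
  rec <- rec[!unk]

  bad_baf <- !is.finite(rec$baf) | rec$baf < 0 | rec$baf > 1
  drops["bad_baf"] <- sum(bad_baf)
  rec <- rec[!bad_baf]
  bad_lrr <- !is.finite(rec$lrr)
  drops["bad_lrr"] <- sum(bad_lrr)
  rec <- rec[!bad_lrr]

  rec[, chrom := chrom_factor(chrom)]
  rec[, pos := as.integer(round(pos))]
  data.table::setcolorder(rec, c("snp_id", "chrom", "pos", "baf", "lrr"))
  track <- new_signal_track(rec, sample_id, sorted = FALSE,
                            drop_counts = drops, n_input = n_input)
  if (sort) track <- ensure_sorted(track) else track
}

#' Sort a signal track by genomic position
#'
#' Sorting by chromosome (canonical order 1-22, X, Y) and position is the
#' first step of detection; a track already in order is detected in one
#' linear scan and returned unchanged with `presorted = TRUE`. Ties at
#' identical (chrom, pos) are broken deterministically by probe id.
#'
#' @param track a `signal_track`.
#' @return the track with `sorted = TRUE`; `presorted` records whether the
#'   input was already in order.
#' @export
ensure_sorted <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  if (isTRUE(track$sorted)) return(track)
  p <- track$probes
  pre <- .is_track_sorted(p)
  if (!pre) {
    ord <- order(p$chrom, p$pos, p$snp_id, method = "radix")
    track$probes <- p[ord]
  }
  track$sorted <- TRUE
  track$presorted <- pre
  track
}

.is_track_sorted <- function(p) {
  if (nrow(p) < 2L) return(TRUE)
  ch <- as.integer(p$chrom)
  d_ch <- diff(ch)
  if (any(d_ch < 0L)) return(FALSE)
  same <- d_ch == 0L
  d_pos <- diff(p$pos)
  if (any(same & d_pos < 0L)) return(FALSE)
  tie <- same & d_pos == 0L
  if (any(tie)) {
    i <- which(tie)
    if (any(p$snp_id[i] > p$snp_id[i + 1L])) return(FALSE)
  }
  TRUE
}

#' Write a signal track to a tab-delimited file
#'
#' Produces the standard five-column export (`SNP Name`, `Chr`, `Position`,
#' `B Allele Freq`, `Log R Ratio`), re-readable by [parse_signal_file()].
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @param eol line terminator; use `"\r\n"` to emulate a Windows export.
#' @export
write_signal_file <- function(track, path, eol = "\n") {
  out <- track$probes[, .(`SNP Name` = snp_id, Chr = as.character(chrom),
                          Position = pos, `B Allele Freq` = baf,
                          `Log R Ratio` = lrr)]
  data.table::fwrite(out, path, sep = "\t", eol = eol, quote = FALSE)
  invisible(path)
}

#' Write mosaic calls to BED or TSV
#'
#' TSV output keeps internal 1-based inclusive coordinates and carries the
#' state, cell-fraction estimate and evidence counts. BED output converts to
#' 0-based half-open coordinates with `name` = state and `score` = number of
#' deviating probes.
#'
#' @param calls a `data.table` of refined calls (see [refine_breakpoints()])
#'   or a `mosaic_result`.
#' @param path output path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (inherits(calls, "mosaic_result")) calls <- calls$calls
  cols <- c("sample_id", "chrom", "start_bp", "end_bp", "length_bp", "state",
            "cell_fraction", "n_windows", "n_dev_probes", "clearing_ratio_min")
  cols <- intersect(cols, names(calls))
  dt <- calls[, ..cols]
  data.table::setorderv(dt, intersect(c("sample_id", "chrom", "start_bp"), cols))
  if (format == "tsv") {
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  } else {
    bed <- dt[, .(chrom = as.character(chrom), start = start_bp - 1L,
                  end = end_bp, name = paste(sample_id, state, sep = "|"),
                  score = n_dev_probes)]
    header <- "#chrom\tstart\tend\tname\tscore"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(bed) > 0)
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
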