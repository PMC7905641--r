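# Internal helpers shared across modules.

# Canonical chromosome order used throughout: autosomes then X, Y.
# Mitochondrial and alternative contigs are not part of the recognized set.
CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels to the canonical set
#'
#' Strips a leading "chr" prefix, maps numeric aliases 23/24 to X/Y and the
#' pseudoautosomal label "XY" to X. Labels outside 1-22, X, Y (e.g. MT, alt
#' contigs) come back as `NA` so callers can drop them.
#'
#' @param x character vector of chromosome labels.
#' @return character vector with unrecognized labels set to `NA`.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "XY"] <- "X"  # pseudoautosomal probes are placed on X
  x[!x %in% CHROM_LEVELS] <- NA_character_
  x
}

chrom_factor <- function(x) factor(x, levels = CHROM_LEVELS)

# Population standard deviation (denominator n), NA below 2 observations.
pop_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / n)
}

# Quartiles by linear interpolation between order statistics
# (stats::quantile type 7). Kept in one place so the definition is
# swappable package-wide.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
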