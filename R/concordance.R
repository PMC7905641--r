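# Sample-level majority-vote concordance between mosaic callers.

#' Build a caller membership table
#'
#' Sample-level concordance: each row is a sample, each column a caller,
#' and a flag marks the sample as mosaic-positive for that caller. Samples
#' negative for every caller are excluded -- the all-negative background is
#' not well defined in a multi-caller comparison without a shared truth set.
#'
#' @param x either a named list of character vectors (positive sample ids
#'   per caller) or a logical matrix with callers as columns.
#' @return a `membership_table`: logical matrix, rownames are sample ids.
#' @export
membership_table <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("caller list must be named")
    if (anyDuplicated(names(x))) stop("duplicate caller names")
    samples <- sort(unique(unlist(x, use.names = FALSE)))
    m <- vapply(x, function(ids) samples %in% ids,
                logical(length(samples)))
    if (length(samples) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(samples, names(x)))
    rownames(m) <- samples
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "logical"
    if (is.null(colnames(m))) stop("membership matrix must have caller column names")
    if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
    allneg <- rowSums(m) == 0L
    if (any(allneg)) {
      message(sprintf("dropping %d sample(s) negative for every caller", sum(allneg)))
      m <- m[!allneg, , drop = FALSE]
    }
  }
  if (ncol(m) < 2L) stop("at least 2 callers required")
  structure(m, class = c("membership_table", class(m)))
}

#' Expand Venn subset counts into a membership table
#'
#' Convenience constructor for published Venn diagrams: subset keys are
#' caller names joined by `&` (e.g. `"MONTAGE&MoCha"`).
#'
#' @param counts named integer vector of per-subset sample counts.
#' @param callers caller names defining column order.
#' @return a `membership_table`.
#' @export
membership_from_venn <- function(counts, callers) {
  rows <- list()
  ids <- character()
  for (key in names(counts)) {
    members <- strsplit(key, "&", fixed = TRUE)[[1]]
    if (!all(members %in% callers))
      stop(sprintf("subset '%s' names unknown caller(s)", key))
    n <- counts[[key]]
    if (n == 0) next
    rows[[key]] <- matrix(rep(callers %in% members, n), nrow = n, byrow = TRUE)
    ids <- c(ids, sprintf("%s_%d", gsub("&", ".", key), seq_len(n)))
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, callers)
  membership_table(m)
}

#' Exact Venn partition counts
#'
#' @param mt a `membership_table`.
#' @return named integer vector over all non-empty caller subsets (keys
#'   joined by `&`, ordered by subset size then caller order); counts sum
#'   to the number of samples.
#' @export
venn_counts <- function(mt) {
  callers <- colnames(mt)
  k <- length(callers)
  subsets <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size, simplify = FALSE)
    for (s in cmb) subsets[[paste(callers[s], collapse = "&")]] <- s
  }
  pat <- apply(mt, 1L, function(r) paste(callers[r], collapse = "&"))
  counts <- vapply(names(subsets), function(key) sum(pat == key), integer(1))
  counts
}

#' Majority-vote truth set
#'
#' Samples flagged by at least two callers are taken as true positives
#' (for two callers this is the intersection).
#'
#' @param mt a `membership_table`.
#' @return list with `n_true` and `samples` (the qualifying ids).
#' @export
majority_vote_truth <- function(mt) {
  hit <- rowSums(mt) >= 2L
  list(n_true = sum(hit), samples = rownames(mt)[hit])
}

#' Majority-vote sensitivity of one caller
#'
#' Fraction of majority-vote true positives the caller recovers:
#' `1 - missed/n_true`.
#'
#' @param mt a `membership_table`.
#' @param caller caller (column) name.
#' @return sensitivity in `[0, 1]`, or `NA` when no sample is supported by
#'   two callers.
#' @export
sensitivity_estimate <- function(mt, caller) {
  j <- .caller_index(mt, caller)
  truth <- rowSums(mt) >= 2L
  n_true <- sum(truth)
  if (n_true == 0L) return(NA_real_)
  sum(truth & mt[, j]) / n_true
}

#' Majority-vote true-positive rate (accuracy) of one caller
#'
#' Under the assumption that samples called by only one caller are false
#' positives: the fraction of the caller's positives that are supported by
#' at least one other caller. The false-positive rate is its complement.
#'
#' @inheritParams sensitivity_estimate
#' @return true-positive rate in `[0, 1]`.
#' @export
tpr_estimate <- function(mt, caller) {
  j <- .caller_index(mt, caller)
  called <- mt[, j]
  if (!any(called)) stop(sprintf("caller '%s' has no positive samples", caller))
  sum(called & rowSums(mt) >= 2L) / sum(called)
}

.caller_index <- function(mt, caller) {
  j <- match(caller, colnames(mt))
  if (is.na(j)) stop(sprintf("unknown caller '%s'", caller))
  j
}

#' All concordance metrics in one pass
#'
#' @param mt a `membership_table`.
#' @return a `concordance_metrics` list: `venn` (subset counts), `n_true`,
#'   and a per-caller `data.table` with `sensitivity`, `tpr` and
#'   `fpr = 1 - tpr`.
#' @export
concordance_metrics <- function(mt) {
  callers <- colnames(mt)
  per <- data.table::data.table(
    caller = callers,
    n_called = colSums(mt),
    sensitivity = vapply(callers, function(cl) sensitivity_estimate(mt, cl), 0),
    tpr = vapply(callers, function(cl) tpr_estimate(mt, cl), 0))
  per[, fpr := 1 - tpr]
  structure(list(venn = venn_counts(mt),
                 n_true = majority_vote_truth(mt)$n_true,
                 per_caller = per[]),
            class = "concordance_metrics")
}

#' @export
print.concordance_metrics <- function(x, ...) {
  cat(sprintf("<concordance_metrics> %d majority-vote true positives\n", x$n_true))
  cat("  Venn counts:\n")
  for (key in names(x$venn)) cat(sprintf("    %-30s %d\n", key, x$venn[[key]]))
  print(x$per_caller)
  invisible(x)
}
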