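# Expression profiling summaries: read-length distributions, the tsRNA
# fraction of total small-RNA reads, class frequencies, positional coverage
# along parent tRNAs, and reads-per-million ("TPM") normalisation. "TPM" here
# is transcripts-per-million in the small-RNA sense: count / total mapped
# reads * 1e6, with no transcript-length correction, since discrete
# fragments are counted rather than sampled proportionally to length.

frag_annotation <- function(x, what = "fragment annotations") {
  if (is.null(x$fragments))
    stop(sprintf("this trf_counts object carries no %s", what), call. = FALSE)
  x$fragments[match(rownames(x$counts), x$fragments$license_plate), ,
              drop = FALSE]
}

#' Fragment-length distribution of one sample
#'
#' @param x A `trf_counts` object with fragment annotations, or a
#'   long-format records data frame from [collapse_and_count()].
#' @param sample_id Sample to summarise.
#' @return Named numeric vector: fraction of tsRNA reads per observed
#'   fragment length; fractions sum to 1. Empty (with a warning) if the
#'   sample has no tsRNA reads.
#' @export
length_histogram <- function(x, sample_id) {
  if (inherits(x, "trf_counts")) {
    cnt <- x$counts[, sample_id]
    len <- nchar(frag_annotation(x)$tsrna_seq)
  } else {
    rows <- x[x$sample_id == sample_id, , drop = FALSE]
    cnt <- rows$count
    len <- nchar(rows$tsrna_seq)
  }
  keep <- cnt > 0
  if (!any(keep)) {
    warning(sprintf("sample %s has no tsRNA reads", sample_id))
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- tapply(cnt[keep], len[keep], sum)
  c(tab / sum(tab))
}

#' Fraction of total reads that are tsRNAs, per sample
#'
#' @param x A `trf_counts` object.
#' @return Named numeric vector in `[0,1]`; `NA` (with a warning) for
#'   samples whose total is zero.
#' @export
tsrna_fraction <- function(x) {
  stopifnot(inherits(x, "trf_counts"))
  tot <- x$totals
  frac <- colSums(x$counts) / tot
  if (any(tot == 0)) {
    warning("samples with zero total reads: fraction undefined")
    frac[tot == 0] <- NA_real_
  }
  frac
}

#' Class frequency distribution of one sample
#'
#' @inheritParams length_histogram
#' @return Named numeric vector of fractions over the observed class labels
#'   (the six tRF classes plus `unclassified`); sums to 1.
#' @export
class_fractions <- function(x, sample_id) {
  if (inherits(x, "trf_counts")) {
    cnt <- x$counts[, sample_id]
    cls <- frag_annotation(x)$class_label
  } else {
    rows <- x[x$sample_id == sample_id, , drop = FALSE]
    cnt <- rows$count
    cls <- rows$class_label
  }
  keep <- cnt > 0
  if (!any(keep)) {
    warning(sprintf("sample %s has no tsRNA reads", sample_id))
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- tapply(cnt[keep], cls[keep], sum)
  c(tab / sum(tab))
}

#' Positional start/end coverage along one parent tRNA
#'
#' Tallies, for each position of the extended reference, how many distinct
#' fragments start (first base) and end (last base) there. One unit per
#' fragment record, so the start-depth sums to the number of placed
#' fragments.
#'
#' @param x A `trf_counts` with fragment annotations, or a records data
#'   frame with `ref_id`, `start`, `end`.
#' @param ref The `mature_reference` to profile.
#' @return List with integer vectors `start_depth` and `end_depth`, each of
#'   length `nchar(ref$extended_seq)`.
#' @export
positional_coverage <- function(x, ref) {
  stopifnot(inherits(ref, "mature_reference"))
  rec <- if (inherits(x, "trf_counts")) frag_annotation(x) else x
  rec <- rec[!is.na(rec$ref_id) & rec$ref_id == ref$trna_id, , drop = FALSE]
  n <- nchar(ref$extended_seq)
  start_depth <- integer(n)
  end_depth <- integer(n)
  if (nrow(rec)) {
    s <- table(factor(rec$start + 1L, levels = seq_len(n)))
    e <- table(factor(rec$end, levels = seq_len(n)))  # last base = end - 1 (0-based)
    start_depth <- as.integer(s)
    end_depth <- as.integer(e)
  }
  list(start_depth = start_depth, end_depth = end_depth)
}

#' Reads-per-million normalisation
#'
#' `tpm = count / per-sample total * 1e6`. Invariant under uniform library
#' scaling and monotone in counts.
#'
#' @param x A `trf_counts` object, or a counts matrix (then `totals` must be
#'   given).
#' @param totals Named per-sample totals when `x` is a bare matrix.
#' @return Numeric matrix of the same shape as the counts.
#' @export
tpm <- function(x, totals = NULL) {
  if (inherits(x, "trf_counts")) {
    counts <- x$counts
    totals <- x$totals
  } else {
    counts <- as.matrix(x)
    if (is.null(totals)) stop("totals required for a bare matrix", call. = FALSE)
    totals <- totals[colnames(counts)]
  }
  if (any(totals <= 0))
    stop("per-sample totals must be positive for TPM", call. = FALSE)
  sweep(counts, 2, totals, "/") * 1e6
}
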