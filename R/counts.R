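# The tsRNA-by-sample count container used by profiling and differential
# expression. `totals` are per-sample total small-RNA read counts (the
# denominator of fractions and reads-per-million); they may exceed the
# column sums because not every read is a tsRNA.

STUDY_DAYS <- c(0L, 7L, 14L, 21L)

#' Construct a tsRNA count container
#'
#' @param counts Integer matrix, rows = fragment (plate) ids, columns =
#'   sample ids.
#' @param sample_meta Data frame with columns `sample_id`, `day`,
#'   `replicate`; default parses `"day<d>_rep<r>"` column names.
#' @param totals Named numeric vector of per-sample total reads; defaults to
#'   the column sums. Must be `>=` the column sums.
#' @param fragments Optional data frame of fragment annotations (e.g. from
#'   [collapse_and_count()]) with at least `license_plate`; used by the
#'   profiling helpers for lengths, classes and positions.
#' @param allowed_days Days permitted in `sample_meta` (default the
#'   adipogenesis timepoints 0, 7, 14, 21); pass `NULL` to allow any.
#' @return Object of class `trf_counts`.
#' @export
trf_counts <- function(counts, sample_meta = NULL, totals = NULL,
                       fragments = NULL, allowed_days = STUDY_DAYS) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(sample_meta)) {
    m <- regmatches(colnames(counts),
                    regexec("^day([0-9]+)_rep([0-9]+)$", colnames(counts)))
    if (any(lengths(m) != 3L))
      stop("cannot parse sample days from column names; supply sample_meta",
           call. = FALSE)
    sample_meta <- data.frame(
      sample_id = colnames(counts),
      day = as.integer(vapply(m, `[`, character(1), 2)),
      replicate = as.integer(vapply(m, `[`, character(1), 3)))
  }
  stopifnot(all(c("sample_id", "day", "replicate") %in% names(sample_meta)),
            setequal(sample_meta$sample_id, colnames(counts)))
  if (!is.null(allowed_days) && !all(sample_meta$day %in% allowed_days))
    stop(sprintf("sample days must be in {%s} (override with allowed_days)",
                 paste(allowed_days, collapse = ",")), call. = FALSE)
  if (is.null(totals)) totals <- colSums(counts)
  totals <- totals[colnames(counts)]
  if (anyNA(totals) || any(totals < colSums(counts)))
    stop("totals must be named per sample and >= the column sums", call. = FALSE)
  if (!is.null(fragments) &&
      !all(rownames(counts) %in% fragments$license_plate))
    stop("fragments table does not cover all count rows", call. = FALSE)
  structure(list(counts = counts, sample_meta = sample_meta,
                 totals = totals, fragments = fragments),
            class = "trf_counts")
}

#' @export
print.trf_counts <- function(x, ...) {
  cat(sprintf("<trf_counts> %d fragments x %d samples (days %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$sample_meta$day)), collapse = "/")))
  invisible(x)
}

#' Assemble a count container from per-sample collapsed records
#'
#' Binds the long-format outputs of [collapse_and_count()] for several
#' samples into one fragment-by-sample matrix.
#'
#' @param records Data frame (rows from one or more samples) as returned by
#'   [collapse_and_count()], or a list of such data frames.
#' @param totals Named numeric vector of per-sample total reads.
#' @param sample_meta Optional sample metadata (see [trf_counts()]).
#' @param allowed_days Passed to [trf_counts()].
#' @return A `trf_counts` object carrying the fragment annotations.
#' @export
count_matrix_from_records <- function(records, totals, sample_meta = NULL,
                                      allowed_days = STUDY_DAYS) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(nrow(records) > 0L)
  tab <- tapply(records$count, list(records$license_plate, records$sample_id),
                sum, default = 0L)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  frag <- records[!duplicated(records$license_plate),
                  setdiff(names(records), c("sample_id", "count")),
                  drop = FALSE]
  trf_counts(counts, sample_meta = sample_meta, totals = totals,
             fragments = frag, allowed_days = allowed_days)
}
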