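# Read processing: adapter trimming, length filtering, and hierarchical
# assignment of small-RNA reads to miRNA, then rRNA, then the extended tRNA
# reference. Alignment is deliberately simple: ungapped placement with at
# most `max_mismatch` mismatches, searched exhaustively, so results are
# deterministic and verifiable against a brute-force oracle.

#' Trim the 3' sequencing adapter from read sequences
#'
#' If the full adapter occurs in the read, the read is truncated at its
#' first occurrence. Otherwise the longest read suffix that exactly matches
#' a prefix of the adapter, with overlap of at least `min_overlap`, is
#' removed. Reads with no such overlap are returned unchanged. A read that
#' is pure adapter trims to the empty string (callers should discard it,
#' e.g. via [length_filter()]).
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence (>= 6 nt).
#' @param min_overlap Minimum suffix/prefix overlap (default 6).
#' @return Character vector of trimmed sequences, same length and names.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 6L) {
  adapter <- as_dna(adapter)
  if (nchar(adapter) < 6L) stop("adapter must be >= 6 nt", call. = FALSE)
  vapply(seqs, function(s) {
    pos <- regexpr(adapter, s, fixed = TRUE)
    if (pos > 0L) return(substr(s, 1L, pos - 1L))
    L <- nchar(s)
    kmax <- min(L, nchar(adapter) - 1L)
    if (kmax >= min_overlap) {
      for (k in kmax:min_overlap) {
        if (substr(s, L - k + 1L, L) == substr(adapter, 1L, k))
          return(substr(s, 1L, L - k))
      }
    }
    s
  }, character(1), USE.NAMES = !is.null(names(seqs)))
}

#' Retain reads within a length window
#'
#' Inclusive bounds; the defaults are the 12-50 nt small-RNA window. A
#' 24-33 nt window is a commonly used stricter variant and can be set via
#' the arguments.
#'
#' @param x Character vector of sequences, or a data frame with a `seq`
#'   column (rows are filtered).
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered object of the same type.
#' @export
length_filter <- function(x, min_len = 12L, max_len = 50L) {
  stopifnot(min_len <= max_len)
  if (is.data.frame(x)) {
    n <- nchar(x$seq)
    x[n >= min_len & n <= max_len, , drop = FALSE]
  } else {
    n <- nchar(x)
    x[n >= min_len & n <= max_len]
  }
}

# Coerce miRNA/rRNA reference input (path, DNAStringSet, or named character)
# to a named character vector.
as_ref_set <- function(x, what) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "DNAStringSet"))
    x <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  if (!is.character(x) || length(x) == 0L || is.null(names(x)))
    stop(sprintf("%s reference must be a non-empty named sequence set", what),
         call. = FALSE)
  x[order(names(x))]
}

# All ungapped placements of `read` in `subject` with <= k mismatches.
# Returns a data.frame(start0, mismatches), possibly empty.
ungapped_hits <- function(read, subject_dna, k) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(read), subject_dna,
                                max.mismatch = k, with.indels = FALSE,
                                fixed = TRUE)
  if (length(m) == 0L) return(data.frame(start0 = integer(), mismatches = integer()))
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(read), subject_dna,
                                    starting.at = Biostrings::start(m),
                                    fixed = TRUE)
  data.frame(start0 = Biostrings::start(m) - 1L, mismatches = as.integer(mm))
}

#' Hierarchically assign reads to miRNA, rRNA, or tRNA references
#'
#' Each read is tested in the fixed order miRNA -> rRNA -> tRNA and receives
#' the first category in which it has an ungapped placement with at most
#' `max_mismatch` mismatches; the search stops at the first category with a
#' hit. Within the tRNA category the single best placement is kept: minimal
#' mismatches, ties broken by lexicographic reference id, then smallest
#' start. Reads placing nowhere are `unmapped`, as are reads with more than
#' 10\% N.
#'
#' @param reads Data frame with columns `read_id` and `seq`, or a character
#'   vector of sequences (ids are generated).
#' @param mirna_ref,rrna_ref miRNA / rRNA reference sets: FASTA path,
#'   `DNAStringSet`, or named character vector.
#' @param trna_refs Named list of `mature_reference` objects (e.g. from
#'   [read_reference()]); reads are placed on the extended sequences.
#' @param max_mismatch Maximum mismatches for a valid placement (default 1).
#' @return Data frame with one row per read: `read_id`, `category` (one of
#'   `miRNA`, `rRNA`, `tRNA`, `unmapped`), `ref_id`, `start`, `end` (0-based
#'   half-open on the reference), `mismatches`.
#' @export
hierarchical_assign <- function(reads, mirna_ref, rrna_ref, trna_refs,
                                max_mismatch = 1L) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%d", seq_along(reads)),
                        seq = unname(reads), stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  mi <- as_ref_set(mirna_ref, "miRNA")
  rr <- as_ref_set(rrna_ref, "rRNA")
  if (!is.list(trna_refs) || length(trna_refs) == 0L)
    stop("tRNA reference set must be non-empty", call. = FALSE)
  if (inherits(trna_refs, "mature_reference")) trna_refs <- list(trna_refs)
  tr_ids <- vapply(trna_refs, `[[`, character(1), "trna_id")
  tr <- stats::setNames(vapply(trna_refs, `[[`, character(1), "extended_seq"),
                        tr_ids)
  tr <- tr[order(names(tr))]
  subjects <- list(miRNA = lapply(mi, Biostrings::DNAString),
                   rRNA  = lapply(rr, Biostrings::DNAString),
                   tRNA  = lapply(tr, Biostrings::DNAString))

  assign_one <- function(s) {
    if (mean(strsplit(s, "", fixed = TRUE)[[1]] == "N") > 0.10) {
      message(sprintf("read with >10%% N assigned unmapped: %s...",
                      substr(s, 1, 12)))
      return(list(category = "unmapped", ref_id = NA_character_,
                  start = NA_integer_, end = NA_integer_,
                  mismatches = NA_integer_))
    }
    for (cat in c("miRNA", "rRNA", "tRNA")) {
      best <- NULL
      for (rid in names(subjects[[cat]])) {
        h <- ungapped_hits(s, subjects[[cat]][[rid]], max_mismatch)
        if (nrow(h) == 0L) next
        h <- h[order(h$mismatches, h$start0), , drop = FALSE][1L, ]
        if (is.null(best) || h$mismatches < best$mismatches)
          best <- list(ref_id = rid, start = h$start0, mismatches = h$mismatches)
        if (best$mismatches == 0L && cat != "tRNA") break
      }
      if (!is.null(best))
        return(list(category = cat, ref_id = best$ref_id,
                    start = best$start,
                    end = best$start + nchar(s),
                    mismatches = best$mismatches))
    }
    list(category = "unmapped", ref_id = NA_character_, start = NA_integer_,
         end = NA_integer_, mismatches = NA_integer_)
  }

  uniq <- unique(reads$seq)
  res <- lapply(uniq, assign_one)
  names(res) <- uniq
  hit <- res[reads$seq]
  data.frame(
    read_id    = reads$read_id,
    category   = vapply(hit, `[[`, character(1), "category"),
    ref_id     = vapply(hit, `[[`, character(1), "ref_id"),
    start      = vapply(hit, `[[`, integer(1), "start"),
    end        = vapply(hit, `[[`, integer(1), "end"),
    mismatches = vapply(hit, `[[`, integer(1), "mismatches"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
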