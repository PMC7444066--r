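# Six-class tRNA fragment taxonomy and license-plate identifiers.
#
# Fragments of tRNAs fall into six canonical classes according to where
# their ends sit relative to the mature tRNA: tRF-5 (5' end to around the
# D-loop/anticodon stem), 5'-half (5' end to the anticodon loop), i-tRF
# (wholly internal), 3'-half (anticodon loop to the 3' CCA end), tRF-3
# (around the T-loop/anticodon stem to the CCA end) and tRF-1 (fragment of
# the primary transcript's 3' trailer, starting right after the mature end).
# Fragments that fit none of these (e.g. spanning the mature/trailer
# boundary, or the full mature body) are reported as "unclassified".

TRF_CLASSES <- c("tRF-5", "tRF-3", "i-tRF", "tRF-1", "5p-half", "3p-half",
                 "unclassified")

#' Classify a tRNA-mapped fragment from its coordinates
#'
#' Applies coordinate rules against the extended reference. With
#' `M = trailer_start` (the mature+CCA length) and `W` the anticodon loop
#' widened by `loop_tol` on both sides, the rules are tested in order:
#' \enumerate{
#'   \item `start >= M - end_tol` -> `tRF-1`
#'   \item `start <= end_tol` and `end` in `W` -> `5p-half`
#'   \item `start <= end_tol` and `end < min(W)` -> `tRF-5`
#'   \item `end >= M - end_tol` and `start` in `W` -> `3p-half`
#'   \item `end >= M - end_tol` and `start > max(W)` -> `tRF-3`
#'   \item `start > end_tol` and `end < M - end_tol` -> `i-tRF`
#'   \item otherwise -> `unclassified`
#' }
#' `end_tol` absorbs one base of end softness (e.g. untemplated additions);
#' `loop_tol` widens the anticodon-loop cut window to cover cleavage in the
#' adjacent stem, which canonical 3'-halves (such as 39-nt halves of a
#' 76-nt tRNA) require.
#'
#' @param start,end Integer vectors, 0-based half-open coordinates on the
#'   extended reference.
#' @param ref A `mature_reference`.
#' @param end_tol Tolerance at the mature 5'/3' ends (default 1).
#' @param loop_tol Widening of the anticodon loop window (default 3).
#' @return Character vector of class labels.
#' @examples
#' ref <- build_mature_reference(make_trna_gene(1, "Thr", "TGT"))
#' classify_fragment(40, 79, ref)  # a 39-nt 3' half
#' @export
classify_fragment <- function(start, end, ref, end_tol = 1L, loop_tol = 3L) {
  stopifnot(inherits(ref, "mature_reference"), length(start) == length(end))
  ext_len <- nchar(ref$extended_seq)
  if (any(start < 0L | end > ext_len | start >= end))
    stop(sprintf("fragment interval outside [0,%d) or empty", ext_len),
         call. = FALSE)
  M <- ref$trailer_start
  w_lo <- ref$landmarks$anticodon_loop[1] - loop_tol   # first position in W
  w_hi <- ref$landmarks$anticodon_loop[2] + loop_tol   # one past last in W
  in_w <- function(p) p >= w_lo & p < w_hi
  out <- character(length(start))
  for (i in seq_along(start)) {
    s <- start[i]; e <- end[i]
    out[i] <-
      if (s >= M - end_tol) "tRF-1"
      else if (s <= end_tol && in_w(e)) "5p-half"
      else if (s <= end_tol && e < w_lo) "tRF-5"
      else if (e >= M - end_tol && in_w(s)) "3p-half"
      else if (e >= M - end_tol && s >= w_hi) "tRF-3"
      else if (s > end_tol && e < M - end_tol) "i-tRF"
      else "unclassified"
  }
  out
}

#' Classify a table of alignment hits
#'
#' Convenience wrapper applying [classify_fragment()] to the tRNA-category
#' rows of a [hierarchical_assign()] result.
#'
#' @param hits Data frame from [hierarchical_assign()].
#' @param refs Named list of `mature_reference` objects.
#' @inheritParams classify_fragment
#' @return `hits` with an added `class_label` column (`NA` for non-tRNA rows).
#' @export
classify_hits <- function(hits, refs, end_tol = 1L, loop_tol = 3L) {
  hits$class_label <- NA_character_
  idx <- which(hits$category == "tRNA")
  for (i in idx) {
    hits$class_label[i] <- classify_fragment(hits$start[i], hits$end[i],
                                             refs[[hits$ref_id[i]]],
                                             end_tol, loop_tol)
  }
  hits
}

# ---------------------------------------------------------------------------
# License plates: deterministic, reversible, alignment-free identifiers of
# the form tRF-<length>-<code>. The sequence is split into consecutive
# 5-mers (final chunk of 1-4 nt allowed); each chunk maps through a fixed
# lookup table to a token over a 32-symbol alphabet that excludes A/C/G/T so
# codes cannot be mistaken for sequence. Chunks of 1-2 nt map to 1-symbol
# tokens, chunks of 3-5 nt to 2-symbol tokens, so a 39-nt sequence always
# yields a 16-character code (7 x 2 + 2). The lookup table used here is the
# package's own deterministic enumeration (chunks in lexicographic order
# paired with consecutive tokens); it has the same shape as, but is not
# identical to, the table behind public tRF databases, so plates are stable
# within analyses run with this package but are not cross-database ids.
# ---------------------------------------------------------------------------

PLATE_ALPHABET <- c(setdiff(LETTERS, c("A", "C", "G", "T")), as.character(0:9))

# chunk (1-5 nt) -> 0-based lexicographic index
chunk_index <- function(chunk) {
  v <- match(strsplit(chunk, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  sum(v * 4L^(rev(seq_along(v)) - 1L))
}

chunk_token <- function(chunk) {
  idx <- chunk_index(chunk)
  if (nchar(chunk) <= 2L) PLATE_ALPHABET[idx + 1L]
  else paste0(PLATE_ALPHABET[idx %/% 32L + 1L], PLATE_ALPHABET[idx %% 32L + 1L])
}

token_chunk <- function(token, chunk_len) {
  syms <- match(strsplit(token, "", fixed = TRUE)[[1]], PLATE_ALPHABET) - 1L
  if (anyNA(syms))
    stop(sprintf("unknown token '%s' in license plate", token), call. = FALSE)
  idx <- if (length(syms) == 1L) syms else syms[1] * 32L + syms[2]
  if (idx >= 4L^chunk_len)
    stop(sprintf("token '%s' does not decode to a %d-mer", token, chunk_len),
         call. = FALSE)
  digits <- integer(chunk_len)
  for (i in rev(seq_len(chunk_len))) {
    digits[i] <- idx %% 4L
    idx <- idx %/% 4L
  }
  paste(DNA_BASES[digits + 1L], collapse = "")
}

#' Encode a fragment sequence as a license plate
#'
#' @param seq Sequence over A/C/G/T (U accepted, mapped to T), 10-60 nt.
#' @param prefix Plate prefix (default `"tRF"`).
#' @return Character scalar `"tRF-<length>-<code>"`.
#' @seealso [decode_license_plate()], [trf_lookup_table()]
#' @export
encode_license_plate <- function(seq, prefix = "tRF") {
  seq <- as_dna(seq)
  check_alphabet(seq)
  n <- nchar(seq)
  if (n < 10L || n > 60L)
    stop("license plates are defined for sequences of 10-60 nt", call. = FALSE)
  starts <- seq.int(1L, n, by = 5L)
  chunks <- substring(seq, starts, pmin(starts + 4L, n))
  sprintf("%s-%d-%s", prefix, n,
          paste(vapply(chunks, chunk_token, character(1)), collapse = ""))
}

#' Decode a license plate back to its sequence
#'
#' Exact inverse of [encode_license_plate()].
#'
#' @param plate Plate string of the form `"<prefix>-<length>-<code>"`.
#' @return The original sequence.
#' @export
decode_license_plate <- function(plate) {
  m <- regmatches(plate, regexec("^[^-]+-([0-9]+)-([0-9A-Z]+)$", plate))[[1]]
  if (length(m) != 3L)
    stop("malformed license plate", call. = FALSE)
  n <- as.integer(m[2]); code <- m[3]
  chunk_lens <- c(rep(5L, n %/% 5L), if (n %% 5L) n %% 5L)
  widths <- ifelse(chunk_lens <= 2L, 1L, 2L)
  if (sum(widths) != nchar(code))
    stop("license plate code length inconsistent with declared length",
         call. = FALSE)
  ends <- cumsum(widths)
  tokens <- substring(code, ends - widths + 1L, ends)
  out <- paste(mapply(token_chunk, tokens, chunk_lens), collapse = "")
  stopifnot(nchar(out) == n)
  out
}

#' The license-plate lookup table
#'
#' All 1364 chunk/token pairs used by [encode_license_plate()], for
#' transparency and external re-implementation.
#'
#' @return Data frame with columns `chunk` and `token`.
#' @export
trf_lookup_table <- function() {
  chunks <- unlist(lapply(1:5, function(L) {
    do.call(paste0, expand.grid(rep(list(DNA_BASES), L))[, L:1, drop = FALSE])
  }))
  data.frame(chunk = chunks,
             token = vapply(chunks, chunk_token, character(1)),
             row.names = NULL)
}

#' Collapse classified hits into counted tsRNA records
#'
#' Reads mapping to the same fragment sequence are collapsed to one record;
#' `count` is the number of supporting reads in the sample, and `parent_ids`
#' lists every reference on which the sequence places exactly (0 mismatches).
#'
#' @param hits Data frame of tRNA-category hits with `class_label` (see
#'   [classify_hits()]).
#' @param refs Named list of `mature_reference` objects.
#' @param sample_id Sample identifier recorded on each record.
#' @return Data frame with columns `license_plate`, `tsrna_seq`,
#'   `class_label`, `ref_id`, `start`, `end`, `parent_ids` (list column),
#'   `sample_id`, `count`.
#' @export
collapse_and_count <- function(hits, refs, sample_id) {
  empty <- data.frame(license_plate = character(), tsrna_seq = character(),
                      class_label = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      sample_id = character(), count = integer(),
                      stringsAsFactors = FALSE)
  empty$parent_ids <- list()
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  stopifnot(all(hits$category == "tRNA"), "class_label" %in% names(hits))
  ext <- vapply(refs, `[[`, character(1), "extended_seq")
  frag <- substr(ext[hits$ref_id], hits$start + 1L, hits$end)
  ord <- order(hits$ref_id, hits$start)
  first <- ord[!duplicated(frag[ord])]
  rec <- hits[first, , drop = FALSE]
  rec_seq <- frag[first]
  counts <- table(frag)
  parents <- lapply(rec_seq, function(s)
    names(ext)[vapply(ext, function(e) grepl(s, e, fixed = TRUE), logical(1))])
  out <- data.frame(
    license_plate = vapply(rec_seq, encode_license_plate, character(1)),
    tsrna_seq = rec_seq,
    class_label = rec$class_label,
    ref_id = rec$ref_id,
    start = rec$start,
    end = rec$end,
    sample_id = sample_id,
    count = as.integer(counts[rec_seq]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$parent_ids <- parents
  out[order(out$license_plate), , drop = FALSE]
}
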