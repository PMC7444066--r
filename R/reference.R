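# Extended mature tRNA references.
#
# The reference used for tsRNA discovery is the spliced mature tRNA body,
# with CCA appended (unconditionally, even when a CCA happens to be encoded
# genomically) and the first 50 genomic nucleotides 3' of the gene appended
# behind the CCA. Fragments of the 3' trailer of the primary transcript
# (tRF-1) therefore map on the same sequence as fragments of the mature
# body. All coordinates are 0-based, half-open, on the mature sense strand.

TRAILER_LEN <- 50L

#' Build the extended mature reference for a tRNA gene
#'
#' Splices out the intron, appends CCA, and appends the first 50 genomic
#' nucleotides 3' of the gene (strand-resolved). Structural landmarks are
#' carried along in spliced-mature coordinates.
#'
#' @param gene A [make_trna_gene()] gene model (class `trna_gene`).
#' @return An object of class `mature_reference` with fields `trna_id`,
#'   `mature_seq`, `mature_cca_seq`, `extended_seq`, `landmarks` (named list
#'   of 0-based half-open intervals: `d_loop`, `anticodon_loop`, `anticodon`,
#'   `t_loop`) and `trailer_start` (= `nchar(mature_cca_seq)`).
#' @examples
#' ref <- build_mature_reference(make_trna_gene(1, "Thr", "TGT"))
#' nchar(ref$extended_seq) - nchar(ref$mature_seq)  # always 53
#' @export
build_mature_reference <- function(gene) {
  stopifnot(inherits(gene, "trna_gene"))
  mature <- gene_mature_seq(gene)
  st <- vapply(gene$exons, `[`, integer(1), 1)
  en <- vapply(gene$exons, `[`, integer(1), 2)
  if (gene$strand == "+") {
    gene_end <- max(en)
    avail <- nchar(gene$genomic_seq) - gene_end
    if (avail < TRAILER_LEN)
      stop(sprintf("gene %s has only %d nt of 3' flank (need %d)",
                   gene$gene_id, avail, TRAILER_LEN), call. = FALSE)
    trailer <- substr(gene$genomic_seq, gene_end + 1L, gene_end + TRAILER_LEN)
  } else {
    gene_start <- min(st)
    if (gene_start < TRAILER_LEN)
      stop(sprintf("gene %s has only %d nt of 3' flank (need %d)",
                   gene$gene_id, gene_start, TRAILER_LEN), call. = FALSE)
    trailer <- revcomp(substr(gene$genomic_seq, gene_start - TRAILER_LEN + 1L,
                              gene_start))
  }
  new_mature_reference(
    trna_id   = gene$gene_id,
    mature_seq = mature,
    trailer    = trailer,
    landmarks  = list(d_loop = gene$d_loop,
                      anticodon_loop = gene$anticodon_loop,
                      anticodon = gene$anticodon_mature_pos,
                      t_loop = gene$t_loop)
  )
}

new_mature_reference <- function(trna_id, mature_seq, trailer, landmarks) {
  mature_cca <- paste0(mature_seq, "CCA")
  ref <- structure(list(
    trna_id = trna_id,
    mature_seq = mature_seq,
    mature_cca_seq = mature_cca,
    extended_seq = paste0(mature_cca, trailer),
    landmarks = lapply(landmarks, as.integer),
    trailer_start = nchar(mature_cca)
  ), class = "mature_reference")
  validate_mature_reference(ref)
  ref
}

validate_mature_reference <- function(ref) {
  n <- nchar(ref$mature_seq)
  if (nchar(ref$extended_seq) != n + 3L + TRAILER_LEN)
    stop("extended length must equal mature length + 3 + 50", call. = FALSE)
  if (substr(ref$extended_seq, ref$trailer_start - 2L, ref$trailer_start) != "CCA")
    stop("extended sequence must carry CCA immediately before the trailer",
         call. = FALSE)
  lm <- ref$landmarks
  need <- c("d_loop", "anticodon_loop", "anticodon", "t_loop")
  if (!all(need %in% names(lm)))
    stop("missing landmark intervals", call. = FALSE)
  for (nm in need) {
    iv <- lm[[nm]]
    if (iv[1] < 0 || iv[2] > n || iv[1] >= iv[2])
      stop(sprintf("landmark %s %s outside mature range [0,%d)", nm, fmt_iv(iv), n),
           call. = FALSE)
  }
  if (!(lm$d_loop[2] <= lm$anticodon_loop[1] &&
        lm$anticodon_loop[2] <= lm$t_loop[1] &&
        lm$anticodon[1] >= lm$anticodon_loop[1] &&
        lm$anticodon[2] <= lm$anticodon_loop[2]))
    stop("landmark intervals out of order", call. = FALSE)
  invisible(ref)
}

#' @export
print.mature_reference <- function(x, ...) {
  cat(sprintf("<mature_reference> %s\n", x$trna_id))
  cat(sprintf("  mature %d nt + CCA + %d-nt trailer = %d nt extended\n",
              nchar(x$mature_seq), TRAILER_LEN, nchar(x$extended_seq)))
  cat(sprintf("  landmarks: d_loop %s, anticodon_loop %s, anticodon %s, t_loop %s\n",
              fmt_iv(x$landmarks$d_loop), fmt_iv(x$landmarks$anticodon_loop),
              fmt_iv(x$landmarks$anticodon), fmt_iv(x$landmarks$t_loop)))
  invisible(x)
}

#' Write a reference set to FASTA plus a landmark sidecar TSV
#'
#' The FASTA records hold the extended sequences; the TSV holds the
#' landmark intervals and `trailer_start`, so that [read_reference()] can
#' reconstruct the full objects.
#'
#' @param refs List of `mature_reference` objects (or a single one).
#' @param fasta,tsv Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference <- function(refs, fasta, tsv) {
  if (inherits(refs, "mature_reference")) refs <- list(refs)
  ids <- vapply(refs, `[[`, character(1), "trna_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate reference id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(refs, `[[`, character(1), "extended_seq"), ids))
  Biostrings::writeXStringSet(seqs, fasta)
  rows <- do.call(rbind, c(list(data.frame(
    trna_id = character(), trailer_start = integer(),
    d_loop_start = integer(), d_loop_end = integer(),
    anticodon_loop_start = integer(), anticodon_loop_end = integer(),
    anticodon_start = integer(), anticodon_end = integer(),
    t_loop_start = integer(), t_loop_end = integer())),
    lapply(refs, function(r) {
      lm <- r$landmarks
      data.frame(trna_id = r$trna_id, trailer_start = r$trailer_start,
                 d_loop_start = lm$d_loop[1], d_loop_end = lm$d_loop[2],
                 anticodon_loop_start = lm$anticodon_loop[1],
                 anticodon_loop_end = lm$anticodon_loop[2],
                 anticodon_start = lm$anticodon[1], anticodon_end = lm$anticodon[2],
                 t_loop_start = lm$t_loop[1], t_loop_end = lm$t_loop[2])
    })))
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, tsv = tsv))
}

#' Read a reference set written by [write_reference()]
#'
#' @param fasta,tsv Paths written by [write_reference()].
#' @return Named list of `mature_reference` objects (names are tRNA ids).
#' @export
read_reference <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids_fa <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids_fa))
    stop("duplicate id in FASTA", call. = FALSE)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("trna_id", "trailer_start", "d_loop_start", "d_loop_end",
            "anticodon_loop_start", "anticodon_loop_end",
            "anticodon_start", "anticodon_end", "t_loop_start", "t_loop_end")
  if (!all(need %in% names(tab)))
    stop("landmark TSV is missing required columns", call. = FALSE)
  if (anyDuplicated(tab$trna_id))
    stop("duplicate id in landmark TSV", call. = FALSE)
  refs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    line <- i + 1L  # header is line 1
    if (anyNA(row) || !is.numeric(row$trailer_start))
      stop(sprintf("malformed TSV row at line %d", line), call. = FALSE)
    if (!row$trna_id %in% ids_fa)
      stop(sprintf("line %d: id '%s' absent from FASTA", line, row$trna_id),
           call. = FALSE)
    ext <- as.character(seqs[[match(row$trna_id, ids_fa)]])
    ts <- as.integer(row$trailer_start)
    if (ts < 4L || ts + TRAILER_LEN != nchar(ext) ||
        substr(ext, ts - 2L, ts) != "CCA")
      stop(sprintf("line %d: trailer_start inconsistent with sequence", line),
           call. = FALSE)
    mature <- substr(ext, 1L, ts - 3L)
    lm <- list(d_loop = c(row$d_loop_start, row$d_loop_end),
               anticodon_loop = c(row$anticodon_loop_start, row$anticodon_loop_end),
               anticodon = c(row$anticodon_start, row$anticodon_end),
               t_loop = c(row$t_loop_start, row$t_loop_end))
    refs[[i]] <- tryCatch(
      new_mature_reference(row$trna_id, mature,
                           substr(ext, ts + 1L, nchar(ext)), lm),
      error = function(e) stop(sprintf("line %d: %s", line, conditionMessage(e)),
                               call. = FALSE))
  }
  stats::setNames(refs, tab$trna_id)
}
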