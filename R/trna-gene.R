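# Synthetic tRNA gene models.
#
# A `trna_gene` is a toy pre-tRNA gene: one or two exons, an optional intron,
# an anticodon, and a 3' genomic flank long enough to donate the 50-nt
# trailer of the extended reference. Coordinates are 0-based, half-open.
# Structural landmarks (D-loop, anticodon loop, anticodon, T-loop) are stored
# in spliced-mature coordinates; defaults follow the canonical cloverleaf
# numbering of a 76-nt tRNA body.

CANONICAL_LANDMARKS <- list(
  d_loop         = c(13L, 22L),
  anticodon_loop = c(31L, 39L),
  anticodon      = c(33L, 36L),
  t_loop         = c(53L, 61L)
)

# Mature position immediately 5' of which tRNA introns are inserted
# (canonical insertion point, one base 3' of the anticodon).
INTRON_INSERTION_POINT <- 38L

#' Generate a synthetic tRNA gene model
#'
#' Builds a reproducible toy pre-tRNA gene: a random mature body of
#' `mature_len` nucleotides carrying the requested anticodon at the canonical
#' anticodon position, optionally interrupted by a 10-20 nt intron inserted
#' one base 3' of the anticodon, followed by a random 3' genomic flank that
#' contains an oligo-T run (a pol III terminator motif) within 60 nt of the
#' gene end.
#'
#' @param seed Integer seed; the same seed yields a byte-identical model.
#' @param isotype Amino-acid code of the tRNA (e.g. `"Thr"`); only used in
#'   the gene identifier.
#' @param anticodon 3-mer over A/C/G/T (U is accepted and mapped to T),
#'   written 5'->3' as it appears in the mature tRNA.
#' @param with_intron Insert an intron?
#' @param gene_id Identifier; default `"tRNA-<isotype>-<anticodon>"`.
#' @param mature_len Length of the spliced mature body (default 76;
#'   allowed 70-90).
#' @param flank_len Length of the 3' genomic flank (>= 60).
#' @param strand `"+"` or `"-"`. Minus-strand genes store the reverse
#'   complement genomic segment with flipped exon coordinates.
#' @param landmarks Optional named list overriding the canonical landmark
#'   intervals (`d_loop`, `anticodon_loop`, `anticodon`, `t_loop`), each a
#'   length-2 integer vector in 0-based half-open mature coordinates.
#' @return An object of class `trna_gene`.
#' @examples
#' g <- make_trna_gene(1, "Thr", "TGT")
#' substr(gene_mature_seq(g), 34, 36)  # the anticodon
#' @export
make_trna_gene <- function(seed, isotype, anticodon, with_intron = FALSE,
                           gene_id = NULL, mature_len = 76L, flank_len = 60L,
                           strand = c("+", "-"), landmarks = NULL) {
  strand <- match.arg(strand)
  anticodon <- as_dna(anticodon)
  if (nchar(anticodon) != 3L)
    stop("anticodon must be a 3-mer", call. = FALSE)
  check_alphabet(anticodon, what = "anticodon")
  mature_len <- as.integer(mature_len)
  if (mature_len < 70L || mature_len > 90L)
    stop("mature_len must lie in [70, 90]", call. = FALSE)
  flank_len <- as.integer(flank_len)
  if (flank_len < 60L)
    stop("flank_len must be >= 60 (the extended reference needs a 50-nt trailer)",
         call. = FALSE)
  lm <- CANONICAL_LANDMARKS
  if (!is.null(landmarks)) lm[names(landmarks)] <- lapply(landmarks, as.integer)

  out <- with_seed(seed, {
    mature <- random_dna(mature_len)
    substr(mature, lm$anticodon[1] + 1L, lm$anticodon[2]) <- anticodon
    intron_seq <- NULL
    if (with_intron) intron_seq <- random_dna(sample(10:20, 1L))
    flank <- random_dna(flank_len)
    # plant a pol III oligo-T terminator within 60 nt of the gene end
    tpos <- sample.int(min(40L, flank_len - 4L), 1L)
    substr(flank, tpos, tpos + 3L) <- "TTTT"
    list(mature = mature, intron = intron_seq, flank = flank)
  })

  ip <- INTRON_INSERTION_POINT
  if (with_intron) {
    il <- nchar(out$intron)
    sense <- paste0(substr(out$mature, 1L, ip), out$intron,
                    substr(out$mature, ip + 1L, mature_len), out$flank)
    exons <- list(c(0L, ip), c(ip + il, ip + il + (mature_len - ip)))
    intron <- c(ip, ip + il)
  } else {
    sense <- paste0(out$mature, out$flank)
    exons <- list(c(0L, mature_len))
    intron <- NULL
  }

  if (strand == "-") {
    L <- nchar(sense)
    flip <- function(iv) c(L - iv[2], L - iv[1])
    genomic_seq <- revcomp(sense)
    exons <- rev(lapply(exons, flip))
    if (!is.null(intron)) intron <- flip(intron)
  } else {
    genomic_seq <- sense
  }

  gene <- structure(list(
    gene_id   = gene_id %||% sprintf("tRNA-%s-%s", isotype, anticodon),
    isotype   = isotype,
    anticodon = anticodon,
    strand    = strand,
    exons     = exons,
    intron    = intron,
    genomic_seq = genomic_seq,
    anticodon_mature_pos = lm$anticodon,
    d_loop = lm$d_loop, anticodon_loop = lm$anticodon_loop, t_loop = lm$t_loop,
    mature_len = mature_len
  ), class = "trna_gene")
  validate_trna_gene(gene)
  gene
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s (%s strand)\n", x$gene_id, x$strand))
  cat(sprintf("  mature body: %d nt; exons: %s%s\n", x$mature_len,
              paste(vapply(x$exons, fmt_iv, character(1)), collapse = ", "),
              if (is.null(x$intron)) "" else sprintf("; intron: %s", fmt_iv(x$intron))))
  cat(sprintf("  anticodon %s at mature %s; 3' flank %d nt\n", x$anticodon,
              fmt_iv(x$anticodon_mature_pos),
              nchar(x$genomic_seq) - max(vapply(x$exons, `[`, integer(1), 2))))
  invisible(x)
}

validate_trna_gene <- function(gene) {
  ex <- gene$exons
  st <- vapply(ex, `[`, integer(1), 1)
  en <- vapply(ex, `[`, integer(1), 2)
  if (any(en <= st)) stop("exon intervals must be non-empty", call. = FALSE)
  if (length(ex) > 1L && any(st[-1] < en[-length(en)]))
    stop("exons must be disjoint and ordered", call. = FALSE)
  if (!is.null(gene$intron)) {
    if (length(ex) != 2L || gene$intron[1] != en[1] || gene$intron[2] != st[2])
      stop("intron must lie strictly between two exons", call. = FALSE)
  }
  spliced <- sum(en - st)
  if (spliced != gene$mature_len)
    stop("exon lengths do not sum to the mature length", call. = FALSE)
  ac <- gene$anticodon_mature_pos; al <- gene$anticodon_loop
  if (!(ac[1] >= al[1] && ac[2] <= al[2]))
    stop("anticodon interval must lie inside the anticodon loop", call. = FALSE)
  if (!(0 <= gene$d_loop[1] && gene$d_loop[1] < gene$d_loop[2] &&
        gene$d_loop[2] <= gene$anticodon_loop[1] &&
        gene$anticodon_loop[1] < gene$anticodon_loop[2] &&
        gene$anticodon_loop[2] <= gene$t_loop[1] &&
        gene$t_loop[1] < gene$t_loop[2] && gene$t_loop[2] <= spliced))
    stop("landmarks must satisfy 0 <= d_loop < anticodon_loop < t_loop < mature length",
         call. = FALSE)
  # 3' flank (mature sense): after last exon on +, before first exon on -
  flank <- if (gene$strand == "+")
    nchar(gene$genomic_seq) - max(en) else min(st)
  if (flank < 60L) stop("3' genomic flank must be >= 60 nt", call. = FALSE)
  invisible(gene)
}

#' Spliced mature sequence of a gene model
#'
#' Concatenates the exon sequences in mature 5'->3' order, reverse
#' complementing for minus-strand genes.
#'
#' @param gene A `trna_gene`.
#' @return Character scalar, the spliced mature body (no CCA).
#' @export
gene_mature_seq <- function(gene) {
  pieces <- vapply(gene$exons, function(iv)
    substr(gene$genomic_seq, iv[1] + 1L, iv[2]), character(1))
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

#' Map a mature-coordinate interval back to genomic intervals
#'
#' Inverts splicing (and strand) for a 0-based half-open interval in
#' spliced-mature coordinates; an interval spanning the intron maps to two
#' genomic pieces. The concatenated (strand-resolved) genomic substrings
#' equal the mature substring.
#'
#' @param gene A `trna_gene`.
#' @param interval Length-2 integer vector, 0-based half-open, in mature
#'   coordinates.
#' @return List of genomic intervals (0-based half-open, in `genomic_seq`
#'   coordinates), ordered 5'->3' along the mature sense.
#' @export
mature_to_genomic <- function(gene, interval) {
  if (interval[1] < 0 || interval[2] > gene$mature_len || interval[1] >= interval[2])
    stop("interval out of mature range", call. = FALSE)
  # exon intervals in mature 5'->3' order with mature offsets
  ex <- gene$exons
  if (gene$strand == "-") ex <- rev(ex)
  off <- 0L
  pieces <- list()
  for (iv in ex) {
    w <- iv[2] - iv[1]
    lo <- max(interval[1], off); hi <- min(interval[2], off + w)
    if (lo < hi) {
      if (gene$strand == "+") {
        pieces[[length(pieces) + 1L]] <- c(iv[1] + (lo - off), iv[1] + (hi - off))
      } else {
        # mature runs right-to-left along the genome
        pieces[[length(pieces) + 1L]] <- c(iv[2] - (hi - off), iv[2] - (lo - off))
      }
    }
    off <- off + w
  }
  pieces
}
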