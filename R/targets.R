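# miRNA-style 3'-UTR target-site scanning for tsRNAs.
#
# The tsRNA is locally aligned against the reverse-complement sense of the
# UTR (so a Watson-Crick pair appears as a character match), with affine
# gaps, a G:U wobble bonus, and doubled substitution weights across the
# seed (tsRNA positions 2-8). The stability proxy counts paired columns
# (-3 per G:C, -2 per A:T, -1 per G:U); more negative values indicate a
# more stable duplex. This is a transparent complementarity scorer, not a
# thermodynamic folding model.

#' Scoring parameters for the target scanner
#'
#' @param match,wobble,mismatch Substitution scores per aligned column
#'   (defaults +5, +1, -3).
#' @param gap_open,gap_extend Affine gap penalties; the first gapped
#'   position costs `gap_open + gap_extend` (defaults -8, -2).
#' @param seed_start,seed_end 1-based tsRNA positions of the seed
#'   (defaults 2 and 8).
#' @param seed_weight Multiplier on substitution scores at seed positions
#'   (default 2).
#' @param threshold Minimum reported site score (default 80).
#' @param max_sites Maximum number of reported sites (default 10).
#' @return Named list of parameters.
#' @export
target_params <- function(match = 5, wobble = 1, mismatch = -3,
                          gap_open = -8, gap_extend = -2,
                          seed_start = 2L, seed_end = 8L, seed_weight = 2,
                          threshold = 80, max_sites = 10L) {
  list(match = match, wobble = wobble, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
       seed_weight = seed_weight, threshold = threshold,
       max_sites = as.integer(max_sites))
}

# Substitution score of tsRNA base xc (weighted w) against rc-UTR base yc.
# In reverse-complement space a WC pair is a character match; the G:U
# wobbles (tsRNA G : UTR U, tsRNA U : UTR G) appear as (G,A) and (T,C).
.pair_type <- function(xc, yc) {
  if (xc == yc) "match"
  else if ((xc == "G" && yc == "A") || (xc == "T" && yc == "C")) "wobble"
  else "mismatch"
}

# Local affine-gap alignment of x (tsRNA) against y (a segment of the
# reverse-complemented UTR). Returns NULL when the best score is <= 0,
# otherwise list(score, pairs = data.frame(tsrna_pos, y_pos, type),
# pairing_string, y_range = c(first, last) 1-based consumed y positions).
.align_local <- function(xc, yc, w, par) {
  m <- length(xc); n <- length(yc)
  NEG <- -1e9
  go <- par$gap_open; ge <- par$gap_extend
  sc <- matrix(0, m, n)
  ty <- matrix("", m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    t <- .pair_type(xc[i], yc[j])
    ty[i, j] <- t
    base <- switch(t, match = par$match, wobble = par$wobble,
                   mismatch = par$mismatch)
    sc[i, j] <- w[i] * base
  }
  M <- matrix(NEG, m + 1L, n + 1L); M[1, ] <- 0; M[, 1] <- 0
  X <- matrix(NEG, m + 1L, n + 1L)
  Y <- matrix(NEG, m + 1L, n + 1L)
  PM <- matrix(0L, m + 1L, n + 1L)  # 0 start, 1 M, 2 X, 3 Y
  PX <- matrix(0L, m + 1L, n + 1L)  # 1 from M, 2 extend
  PY <- matrix(0L, m + 1L, n + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      prev <- c(0, M[i, j], X[i, j], Y[i, j])
      k <- which.max(prev)
      M[i + 1L, j + 1L] <- sc[i, j] + prev[k]
      PM[i + 1L, j + 1L] <- k - 1L
      xo <- M[i, j + 1L] + go; xe <- X[i, j + 1L]
      if (xo >= xe) { X[i + 1L, j + 1L] <- xo + ge; PX[i + 1L, j + 1L] <- 1L }
      else          { X[i + 1L, j + 1L] <- xe + ge; PX[i + 1L, j + 1L] <- 2L }
      yo <- M[i + 1L, j] + go; ye <- Y[i + 1L, j]
      if (yo >= ye) { Y[i + 1L, j + 1L] <- yo + ge; PY[i + 1L, j + 1L] <- 1L }
      else          { Y[i + 1L, j + 1L] <- ye + ge; PY[i + 1L, j + 1L] <- 2L }
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) return(NULL)
  # traceback from M[bi, bj]
  pairs <- list(); trace <- character(0)
  i <- bi; j <- bj; state <- 1L
  repeat {
    if (state == 1L) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      trace <- c(switch(ty[i, j], match = "M", wobble = "W", mismatch = "X"),
                 trace)
      nxt <- PM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
      if (nxt == 0L) break
      state <- nxt
    } else if (state == 2L) {          # gap in UTR (consumes tsRNA base)
      trace <- c("-", trace)
      nxt <- PX[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (nxt == 1L) 1L else 2L
    } else {                           # gap in tsRNA (consumes UTR base)
      trace <- c("-", trace)
      nxt <- PY[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (nxt == 1L) 1L else 3L
    }
  }
  pm <- do.call(rbind, rev(pairs))
  pdf <- data.frame(tsrna_pos = pm[, 1], y_pos = pm[, 2],
                    type = vapply(seq_len(nrow(pm)),
                                  function(r) ty[pm[r, 1], pm[r, 2]],
                                  character(1)))
  list(score = best, pairs = pdf, pairing_string = paste(trace, collapse = ""),
       y_range = c(j + 1L, bj))
}

#' Scan a 3'-UTR for tsRNA binding sites
#'
#' Reports non-overlapping candidate sites, best score first, down to the
#' score threshold. Site intervals are 0-based half-open on the UTR (sense
#' strand).
#'
#' @param tsrna_seq tsRNA sequence (12-50 nt, A/C/G/T; U mapped to T).
#' @param utr_seq UTR sequence (sense strand).
#' @param utr_id Identifier recorded on the sites (default `"utr"`).
#' @param params Scoring parameters from [target_params()].
#' @return Data frame of class `target_sites`, one row per site: `utr_id`,
#'   `start`, `end`, `score`, `stability_proxy`, `seed_matched`,
#'   `pairing_string` (5'->3' along the tsRNA; `M` match, `W` wobble,
#'   `X` mismatch, `-` gap) and a `pairings` list column of per-column
#'   pairing tables (`tsrna_pos` 1-based, `utr_pos` 0-based, `type`).
#' @examples
#' ts <- "TGGTGTCCTTGGAAAAAGGTTTTCA"
#' utr <- paste0(strrep("A", 30),
#'               as.character(Biostrings::reverseComplement(Biostrings::DNAString(ts))),
#'               strrep("C", 30))
#' scan_utr(ts, utr)[, c("start", "end", "score", "seed_matched")]
#' @export
scan_utr <- function(tsrna_seq, utr_seq, utr_id = "utr",
                     params = target_params()) {
  tsrna_seq <- as_dna(tsrna_seq); utr_seq <- as_dna(utr_seq)
  check_alphabet(tsrna_seq, what = "tsRNA sequence")
  check_alphabet(utr_seq, what = "UTR sequence")
  m <- nchar(tsrna_seq)
  if (m < 12L || m > 50L)
    stop("tsRNA length must be 12-50 nt", call. = FALSE)
  n <- nchar(utr_seq)
  xc <- strsplit(tsrna_seq, "", fixed = TRUE)[[1]]
  yc_full <- strsplit(revcomp(utr_seq), "", fixed = TRUE)[[1]]
  w <- rep(1, m)
  sr <- max(1L, params$seed_start); se <- min(m, params$seed_end)
  w[sr:se] <- params$seed_weight
  masked <- rep(FALSE, n)

  empty <- data.frame(utr_id = character(), start = integer(), end = integer(),
                      score = numeric(), stability_proxy = numeric(),
                      seed_matched = logical(), pairing_string = character(),
                      stringsAsFactors = FALSE)
  empty$pairings <- list()
  sites <- empty

  repeat {
    if (nrow(sites) >= params$max_sites) break
    # maximal unmasked segments of the rc UTR
    r <- rle(!masked)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    segs <- cbind(starts[r$values], ends[r$values])
    best <- NULL; best_off <- 0L
    if (nrow(segs) > 0) for (k in seq_len(nrow(segs))) {
      if (segs[k, 2] - segs[k, 1] + 1L < 3L) next
      aln <- .align_local(xc, yc_full[segs[k, 1]:segs[k, 2]], w, params)
      if (!is.null(aln) && (is.null(best) || aln$score > best$score)) {
        best <- aln; best_off <- segs[k, 1] - 1L
      }
    }
    if (is.null(best) || best$score < params$threshold) break
    yr <- best$y_range + best_off          # 1-based rc coords consumed
    utr_start <- n - yr[2]                 # 0-based half-open on the UTR
    utr_end <- n - yr[1] + 1L
    pr <- best$pairs
    pr$utr_pos <- n - (pr$y_pos + best_off)
    pr <- pr[, c("tsrna_pos", "utr_pos", "type")]
    seed_cols <- pr[pr$tsrna_pos >= sr & pr$tsrna_pos <= se, , drop = FALSE]
    seed_matched <- nrow(seed_cols) == (se - sr + 1L) &&
      all(seed_cols$type == "match")
    gc_pair <- sum(pr$type == "match" &
                     xc[pr$tsrna_pos] %in% c("G", "C"))
    at_pair <- sum(pr$type == "match" &
                     xc[pr$tsrna_pos] %in% c("A", "T"))
    gu_pair <- sum(pr$type == "wobble")
    row <- data.frame(utr_id = utr_id, start = utr_start, end = utr_end,
                      score = best$score,
                      stability_proxy = -(3 * gc_pair + 2 * at_pair + gu_pair),
                      seed_matched = seed_matched,
                      pairing_string = best$pairing_string,
                      stringsAsFactors = FALSE)
    row$pairings <- list(pr)
    sites <- rbind(sites, row)
    masked[yr[1]:yr[2]] <- TRUE
  }
  class(sites) <- c("target_sites", class(sites))
  sites
}

#' Mutate a predicted binding site to break seed pairing
#'
#' Substitutes `n_mut` paired UTR positions inside the site's seed-pairing
#' region (the UTR bases paired with tsRNA seed positions) with
#' non-complementary, non-wobble bases, choosing the positions whose
#' substitution loses the most score. Mirrors the construction of a mutant
#' reporter UTR from a wild-type one. The UTR length is unchanged.
#'
#' @param utr_seq The wild-type UTR (sense strand).
#' @param site One row of a [scan_utr()] result (keep it as a data frame,
#'   e.g. `sites[1, ]`).
#' @param tsrna_seq The tsRNA the site was predicted for.
#' @param n_mut Number of positions to substitute (default 4).
#' @param seed Integer seed for tie-breaking among equivalent replacement
#'   bases; a fixed seed yields an identical mutant.
#' @param params The [target_params()] the site was scanned with.
#' @return The mutated UTR sequence.
#' @export
mutate_site <- function(utr_seq, site, tsrna_seq, n_mut = 4L, seed = 1L,
                        params = target_params()) {
  utr_seq <- as_dna(utr_seq); tsrna_seq <- as_dna(tsrna_seq)
  stopifnot(is.data.frame(site), nrow(site) == 1L, "pairings" %in% names(site))
  if (n_mut == 0L) return(utr_seq)
  pr <- site$pairings[[1]]
  sr <- params$seed_start; se <- params$seed_end
  cand <- pr[pr$tsrna_pos >= sr & pr$tsrna_pos <= se & pr$type != "gap", ,
             drop = FALSE]
  if (nrow(cand) < n_mut)
    stop(sprintf("site has only %d paired seed positions (n_mut = %d)",
                 nrow(cand), n_mut), call. = FALSE)
  loss <- ifelse(cand$type == "match", params$match - params$mismatch,
                 ifelse(cand$type == "wobble", params$wobble - params$mismatch, 0))
  cand <- cand[order(-loss, cand$tsrna_pos), , drop = FALSE][seq_len(n_mut), ]
  xc <- strsplit(tsrna_seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wobble_partner <- c(G = "T", T = "G", A = "", C = "")  # UTR base giving G:U
  out <- utr_seq
  with_seed(seed, {
    for (r in seq_len(nrow(cand))) {
      p <- cand$utr_pos[r]
      t <- xc[cand$tsrna_pos[r]]
      cur <- substr(out, p + 1L, p + 1L)
      bad <- c(comp[[t]], wobble_partner[[t]], cur)
      choices <- setdiff(DNA_BASES, bad)
      pick <- if (length(choices) == 1L) choices else sample(choices, 1L)
      substr(out, p + 1L, p + 1L) <- pick
    }
  })
  out
}
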