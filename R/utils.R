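# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the RNG to a fixed seed for the duration of `code` and restores the
#' caller's RNG state afterwards, so that seeded generators do not disturb
#' the session.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA string(s); vectorised over n sequences of length len.
random_dna <- function(len, n = 1L) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

# Reverse complement of plain character vectors (DNA alphabet, N allowed).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Map RNA-style U to T and upper-case; the package works on the DNA alphabet.
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Check a sequence is over a restricted alphabet.
check_alphabet <- function(x, allowed = DNA_BASES, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(allowed, collapse = "")), x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {%s}", what,
                 paste(allowed, collapse = ",")), call. = FALSE)
  invisible(x)
}

# 0-based half-open interval formatting for error messages.
fmt_iv <- function(iv) sprintf("[%d,%d)", iv[1], iv[2])

`%||%` <- function(a, b) if (is.null(a)) b else a
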