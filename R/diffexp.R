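# Differential expression of tsRNA counts between two timepoints.
#
# Normalisation is median-of-ratios (computed over fragments detected in
# every sample), and the per-fragment test is an exact conditional binomial
# test on the pooled raw counts of the two groups: conditional on the total
# count of a fragment, the group-B share is binomial with success
# probability equal to group B's share of the summed library sizes. The
# test is exact and assumption-light; it models count (Poisson-like)
# sampling noise but not extra-Poisson biological dispersion, for which it
# is anticonservative (see the methods vignette). Significance calling uses
# joint fold-change, p and Benjamini-Hochberg FDR cut-offs (fold change > 2
# or < 0.5, P < 0.05, FDR < 0.05 by default).

#' Median-of-ratios size factors
#'
#' Size factors are medians, per sample, of the ratios of counts to the
#' row-wise geometric means, computed over rows with nonzero counts in all
#' samples, then rescaled to geometric mean 1. When no row is positive in
#' all samples, the column totals (rescaled to geometric mean 1) are used
#' instead, with a message.
#'
#' @param counts Count matrix (or `trf_counts`).
#' @return Named numeric vector of size factors, geometric mean 1.
#' @export
normalize_size_factors <- function(counts) {
  if (inherits(counts, "trf_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    message("no fragment is detected in all samples; ",
            "falling back to column-total size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("a sample has all-zero counts", call. = FALSE)
  } else {
    sub <- counts[keep, , drop = FALSE]
    loggeo <- rowMeans(log(sub))
    sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - loggeo)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Exact conditional test for differential expression between two groups
#'
#' Per fragment, `log2fc = log2((mean_b + pc) / (mean_a + pc))` on
#' size-factor-normalised counts, and the p-value is from a two-sided exact
#' binomial test of the group-B share of the pooled raw count against the
#' size-proportional null (group B's share of the summed library sizes).
#' FDR is Benjamini-Hochberg across all tested fragments.
#'
#' @param x A `trf_counts` object, or a counts matrix.
#' @param group_a,group_b Character vectors of sample ids (e.g. the day-0
#'   and day-7 replicates).
#' @param pseudocount Added to both normalised means before the fold change
#'   (default 1), so fragments absent in one condition get a finite
#'   fold change.
#' @param size_factors Optional pre-computed size factors; default
#'   [normalize_size_factors()] on the used samples.
#' @param totals Library sizes for the binomial null; default the object's
#'   `totals` (or column sums for a bare matrix).
#' @return Data frame of class `trf_de`: `plate_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `p_value`, `fdr`, `significant` (at the default cut-offs of
#'   [call_significant()]).
#' @export
de_test <- function(x, group_a, group_b, pseudocount = 1,
                    size_factors = NULL, totals = NULL) {
  if (inherits(x, "trf_counts")) {
    counts <- x$counts
    totals <- totals %||% x$totals
  } else {
    counts <- as.matrix(x)
    totals <- totals %||% colSums(counts)
  }
  stopifnot(length(group_a) > 0L, length(group_b) > 0L,
            all(c(group_a, group_b) %in% colnames(counts)))
  if (sum(totals[group_a]) == 0 || sum(totals[group_b]) == 0)
    stop("a group has all-zero library sizes", call. = FALSE)
  use <- c(group_a, group_b)
  sf <- size_factors %||% normalize_size_factors(counts[, use, drop = FALSE])
  norm <- sweep(counts[, use, drop = FALSE], 2, sf[use], "/")
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  xa <- rowSums(counts[, group_a, drop = FALSE])
  xb <- rowSums(counts[, group_b, drop = FALSE])
  p0 <- sum(totals[group_b]) / (sum(totals[group_a]) + sum(totals[group_b]))
  p <- vapply(seq_along(xa), function(i) {
    n <- xa[i] + xb[i]
    if (n == 0) return(1)
    stats::binom.test(xb[i], n, p = p0, alternative = "two.sided")$p.value
  }, numeric(1))
  res <- data.frame(
    plate_id = rownames(counts) %||% sprintf("row%d", seq_along(xa)),
    mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$significant <- res$plate_id %in% call_significant(res)$plate_id
  class(res) <- c("trf_de", class(res))
  res
}

#' Apply fold-change / p / FDR significance cut-offs
#'
#' A fragment is called significant when its fold change exceeds `fc_hi` or
#' is below `fc_lo` (fold change > 2 is equivalent to log2FC > 1), its
#' p-value is below `alpha_p`, and its FDR is below `alpha_fdr`.
#'
#' @param results A `trf_de` data frame from [de_test()].
#' @param fc_hi,fc_lo Fold-change cut-offs (defaults 2 and 0.5).
#' @param alpha_p,alpha_fdr P-value and FDR cut-offs (defaults 0.05).
#' @return The significant subset of `results`, with `significant = TRUE`,
#'   sorted by FDR.
#' @export
call_significant <- function(results, fc_hi = 2, fc_lo = 0.5,
                             alpha_p = 0.05, alpha_fdr = 0.05) {
  fc <- 2^results$log2fc
  keep <- (fc > fc_hi | fc < fc_lo) &
    results$p_value < alpha_p & results$fdr < alpha_fdr
  out <- results[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  out[order(out$fdr, out$p_value), , drop = FALSE]
}

#' @export
print.trf_de <- function(x, ...) {
  if (!is.null(x$significant))
    cat(sprintf("<trf_de> %d fragments tested, %d significant\n",
                nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x[order(x$fdr), ], 10), ...)
  invisible(x)
}
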