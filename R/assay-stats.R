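# Validation-layer statistics: 2^-ddCt relative quantification for qPCR and
# two-group / multi-group location comparisons.

#' Relative expression by the 2^-ddCt method
#'
#' `ddct = (Ct_target,treated - Ct_reference,treated) -
#' (Ct_target,control - Ct_reference,control)`; the fold change of the
#' target in treated relative to control is `2^(-ddct)`. Adding a constant
#' to all four Ct values leaves the result unchanged.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Threshold-cycle values (finite, positive).
#' @param gene Optional gene label.
#' @return Object of class `ddct_result` with `gene`, `delta_ct_treated`,
#'   `delta_ct_control`, `ddct`, `fold_change`.
#' @examples
#' ddct_fold_change(20, 15, 24, 15)$fold_change  # 16
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control,
                             gene = "target") {
  ct <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(ct)) || any(ct <= 0))
    stop("all Ct values must be finite and positive", call. = FALSE)
  d_tr <- ct_target_treated - ct_ref_treated
  d_co <- ct_target_control - ct_ref_control
  ddct <- d_tr - d_co
  structure(list(gene = gene, delta_ct_treated = d_tr,
                 delta_ct_control = d_co, ddct = ddct,
                 fold_change = 2^(-ddct)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s: ddCt = %.3f cycles, fold change = %.3f\n",
              x$gene, x$ddct, x$fold_change))
  invisible(x)
}

#' Compare numeric groups by t test or one-way ANOVA
#'
#' Two groups are compared by a two-sample, two-tailed Student t test
#' (equal variances by default; set `welch = TRUE` for the Welch variant);
#' three or more groups by a one-way ANOVA F test. When every observation
#' is identical the comparison is degenerate and p = 1 is returned by
#' convention, with a message.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) t test for two groups?
#' @return List with `statistic`, `p_value`, `method`.
#' @export
group_compare <- function(groups, welch = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    message("all observations identical: p = 1 by convention")
    return(list(statistic = 0,
                p_value = 1,
                method = "degenerate (zero variance, equal means)"))
  }
  if (length(groups) == 2L) {
    if (stats::var(groups[[1]]) == 0 && stats::var(groups[[2]]) == 0) {
      # zero within-group variance but different means
      message("zero within-group variance with unequal means: p = 0 by convention")
      return(list(statistic = Inf, p_value = 0,
                  method = "degenerate (zero variance, unequal means)"))
    }
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = !welch,
                        alternative = "two.sided")
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         method = tt$method)
  } else {
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    list(statistic = unname(ow$statistic), p_value = ow$p.value,
         method = "one-way ANOVA")
  }
}
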