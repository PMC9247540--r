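# Correlation, four-quadrant trending concordance, and the paired/unpaired
# comparison tests (with normality-based routing) used for the
# before/after and responder/non-responder tables.

#' Linear correlation (r-squared and p-value)
#'
#' Pearson correlation on pairwise-complete observations, with the
#' standard t-based two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r2`, `r`, `p`, `n`.
#' @export
linear_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y)
  list(r2 = unname(ct$estimate)^2, r = unname(ct$estimate),
       p = ct$p.value, n = length(x))
}

#' Four-quadrant trending concordance
#'
#' The concordance rate of paired percent changes: pairs where both
#' `|dx|` and `|dy|` fall inside the central exclusion square are dropped,
#' and the rate is the percentage of remaining pairs whose changes agree
#' in sign.
#'
#' @param dx,dy Paired percent changes.
#' @param exclusion Half-width of the central exclusion square, percent
#'   (default 10; the conventional choice for trending analysis).
#' @return An object of class `concordance_result`: list with `rate`
#'   (percent), `n_used`, `n_total`, `exclusion_pct`.
#' @export
#' @examples
#' four_quadrant_concordance(c(5, -5, 5, -5), c(5, 5, -5, -5), exclusion = 0)
four_quadrant_concordance <- function(dx, dy, exclusion = 10) {
  keep <- !is.na(dx) & !is.na(dy)
  dx <- dx[keep]; dy <- dy[keep]
  n_total <- length(dx)
  inside <- abs(dx) < exclusion & abs(dy) < exclusion
  dx <- dx[!inside]; dy <- dy[!inside]
  if (length(dx) == 0) stop("all pairs fall inside the exclusion zone")
  rate <- 100 * mean(sign(dx) == sign(dy))
  structure(list(rate = rate, n_used = length(dx), n_total = n_total,
                 exclusion_pct = exclusion),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance rate: %.2f%% (%d of %d pairs used, %g%% exclusion zone)\n",
              x$rate, x$n_used, x$n_total, x$exclusion_pct))
  invisible(x)
}

# Shapiro-Wilk gate: TRUE when normality is not rejected at `alpha`;
# falls back to FALSE (non-parametric route) when the test is undefined
.looks_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
  if (length(x) > 5000) x <- x[seq_len(5000)]
  stats::shapiro.test(x)$p.value >= alpha
}

#' Paired before/after comparison
#'
#' Routes between the paired t-test and the Wilcoxon signed-rank test:
#' differences are checked with Shapiro-Wilk at `alpha_normal`, the t-test
#' is used when normality is not rejected. All-zero differences short-
#' circuit to p = 1 with `test_used = "degenerate"`.
#'
#' @param before,after Paired measurements (>= 3 complete pairs).
#' @param alpha_normal Normality-gate level (default 0.05).
#' @return List with `statistic`, `p`, `test_used`, `n`.
#' @export
compare_paired <- function(before, after, alpha_normal = 0.05) {
  keep <- !is.na(before) & !is.na(after)
  before <- before[keep]; after <- after[keep]
  if (length(before) < 3) stop("need at least 3 complete pairs")
  d <- after - before
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, test_used = "degenerate",
                n = length(d)))
  if (.looks_normal(d, alpha_normal)) {
    tt <- stats::t.test(after, before, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         test_used = "paired_t", n = length(d))
  } else {
    wt <- stats::wilcox.test(after, before, paired = TRUE, exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test_used = "wilcoxon_signed_rank", n = length(d))
  }
}

#' Two-group comparison
#'
#' Routes between Welch's two-sample t-test and the Wilcoxon rank-sum
#' test: both groups must pass the Shapiro-Wilk gate for the t-test to be
#' used.
#'
#' @param a,b The two groups (>= 2 values each).
#' @param alpha_normal Normality-gate level (default 0.05).
#' @return List with `statistic`, `p`, `test_used`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, alpha_normal = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(c(a, b)) == 0)
    return(list(statistic = NA_real_, p = 1, test_used = "degenerate",
                n_a = length(a), n_b = length(b)))
  if (.looks_normal(a, alpha_normal) && .looks_normal(b, alpha_normal)) {
    tt <- stats::t.test(a, b)            # Welch, unequal variances
    list(statistic = unname(tt$statistic), p = tt$p.value,
         test_used = "welch_t", n_a = length(a), n_b = length(b))
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test_used = "wilcoxon_rank_sum", n_a = length(a), n_b = length(b))
  }
}

#' Format a p-value for reports
#'
#' Two decimals above 0.001, `"<0.001"` below.
#' @param p A p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.2f", p))
}
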