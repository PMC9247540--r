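# 2x2 classification at a cutoff and the derived diagnostic metrics:
# Sn/Sp/PPV/NPV with exact Clopper-Pearson intervals, LR+/LR- with
# log-method intervals.

#' Build the 2x2 table at a cutoff
#'
#' Counts true/false positives and negatives when calling a patient
#' test-positive at `score >= cutoff` (direction `"higher"`) or
#' `score <= cutoff` (`"lower"`). Patients with a missing score are dropped
#' and the dropped count reported with a message.
#'
#' @inheritParams empirical_roc
#' @param cutoff The decision threshold.
#' @return An object of class `two_by_two`: list with integer `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
#' @examples
#' classify_at_cutoff(c(50, 45, 30, 20), c(TRUE, TRUE, FALSE, FALSE), 40)
classify_at_cutoff <- function(scores, labels, cutoff, direction = "higher") {
  direction <- .roc_direction(direction)
  cp <- clean_pairs(scores, labels)
  if (cp$n_dropped > 0)
    message(cp$n_dropped, " patient(s) with missing scores dropped")
  test_pos <- if (direction == "higher") cp$scores >= cutoff
              else cp$scores <= cutoff
  structure(list(tp = sum(test_pos & cp$labels),
                 fn = sum(!test_pos & cp$labels),
                 fp = sum(test_pos & !cp$labels),
                 tn = sum(!test_pos & !cp$labels)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"),
                              c("responder", "non-responder")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' Uses the beta-quantile representation of the inverted binomial tails:
#' lower = `qbeta(alpha/2, s, n-s+1)` (0 when s = 0), upper =
#' `qbeta(1-alpha/2, s+1, n-s)` (1 when s = n).
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `metric_ci`: list with `estimate`, `ci`
#'   (length-2 numeric), `method = "clopper_pearson"`; all on the 0-1
#'   scale.
#' @export
#' @examples
#' proportion_ci_exact(12, 13) # 92.3% (64.0%, 99.8%)
proportion_ci_exact <- function(successes, trials, level = 0.95) {
  stopifnot(length(successes) == 1L, length(trials) == 1L)
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop("successes must be in [0, trials]")
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  structure(list(estimate = successes / trials, ci = c(lo, hi),
                 method = "clopper_pearson"),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.4g (%d%% CI %.4g-%.4g, %s)\n", x$estimate,
              round(100 * attr(x, "level", exact = TRUE) %||% 95),
              x$ci[1], x$ci[2], x$method))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-method CI for a likelihood ratio; counts may carry a continuity
# correction already
.lr_ci <- function(lr, num, num_tot, den, den_tot, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.finite(lr) || lr <= 0) return(c(NA_real_, Inf))
  se <- sqrt(1 / num - 1 / num_tot + 1 / den - 1 / den_tot)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Full diagnostic summary of a 2x2 table
#'
#' Sensitivity, specificity, predictive values (exact Clopper-Pearson
#' intervals) and likelihood ratios (log-method intervals):
#' `LR+ = Sn/(1-Sp)`, `LR- = (1-Sn)/Sp`, with
#' `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and the
#' analogous expression for LR-. When any cell is zero a 0.5 continuity
#' correction is applied to all four cells *for the LR intervals only*
#' (with a warning); an infinite LR is reported as such with an open upper
#' interval.
#'
#' @param t A `two_by_two` from [classify_at_cutoff()].
#' @param level Confidence level (default 0.95).
#' @return An object of class `diagnostic_summary`: list of `metric_ci`
#'   objects `sens`, `spec`, `ppv`, `npv`, `lr_pos`, `lr_neg`, plus
#'   `prevalence` and the counts.
#' @export
diagnostic_summary <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  n_pos <- t$tp + t$fn; n_neg <- t$fp + t$tn
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one responder and one non-responder")
  sens <- proportion_ci_exact(t$tp, n_pos, level)
  spec <- proportion_ci_exact(t$tn, n_neg, level)
  ppv <- if (t$tp + t$fp > 0) proportion_ci_exact(t$tp, t$tp + t$fp, level)
         else structure(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                             method = "clopper_pearson"), class = "metric_ci")
  npv <- if (t$tn + t$fn > 0) proportion_ci_exact(t$tn, t$tn + t$fn, level)
         else structure(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                             method = "clopper_pearson"), class = "metric_ci")

  sn <- t$tp / n_pos; sp <- t$tn / n_neg
  lr_pos <- if (sp == 1) Inf else sn / (1 - sp)
  lr_neg <- if (sp == 0) Inf else (1 - sn) / sp

  cells <- c(t$tp, t$fn, t$fp, t$tn)
  corrected <- any(cells == 0)
  if (corrected) {
    warning("zero cell: 0.5 continuity correction applied for LR intervals")
    cells <- cells + 0.5
  }
  ctp <- cells[1]; cfn <- cells[2]; cfp <- cells[3]; ctn <- cells[4]
  lrp_ci <- if (is.infinite(lr_pos)) c(NA_real_, Inf) else
    .lr_ci(lr_pos, ctp, ctp + cfn, cfp, cfp + ctn, level)
  lrn_ci <- if (is.infinite(lr_neg)) c(NA_real_, Inf) else
    .lr_ci(lr_neg, cfn, ctp + cfn, ctn, cfp + ctn, level)

  structure(list(
    sens = sens, spec = spec, ppv = ppv, npv = npv,
    lr_pos = structure(list(estimate = lr_pos, ci = lrp_ci,
                            method = "log_method"), class = "metric_ci"),
    lr_neg = structure(list(estimate = lr_neg, ci = lrn_ci,
                            method = "log_method"), class = "metric_ci"),
    prevalence = n_pos / (n_pos + n_neg),
    counts = t, level = level, lr_corrected = corrected
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  pct <- function(m) sprintf("%s%% (%s-%s%%)",
                             format(round_half_up(100 * m$estimate, 1)),
                             format(round_half_up(100 * m$ci[1], 1)),
                             format(round_half_up(100 * m$ci[2], 1)))
  num <- function(m) sprintf("%.2f (%.2f-%.2f)", m$estimate, m$ci[1], m$ci[2])
  cat("Diagnostic summary (", round(100 * x$level), "% CIs)\n", sep = "")
  cat("  Sensitivity:", pct(x$sens), "\n")
  cat("  Specificity:", pct(x$spec), "\n")
  cat("  PPV:        ", pct(x$ppv), "\n")
  cat("  NPV:        ", pct(x$npv), "\n")
  cat("  LR+:        ", num(x$lr_pos), "\n")
  cat("  LR-:        ", num(x$lr_neg), "\n")
  invisible(x)
}
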