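# Empirical ROC analysis: Mann-Whitney AUC, DeLong structural-components
# variance (covariance for paired markers), and Youden-index cutoff search.
# Cutoff semantics throughout: with direction "higher" a patient is
# test-positive when score >= cutoff; candidate cutoffs are midpoints
# between adjacent distinct observed values plus -Inf/+Inf sentinels, so
# every attainable empirical (Sn, Sp) pair is visited exactly once.

.roc_direction <- function(direction) {
  match.arg(direction, c("higher", "lower"))
}

# orient scores so that larger = more likely positive
.orient <- function(scores, direction) {
  if (direction == "lower") -scores else scores
}

.roc_candidates <- function(scores) {
  v <- sort(unique(scores))
  if (length(v) == 1L) return(c(-Inf, Inf))
  c(-Inf, (v[-length(v)] + v[-1L]) / 2, Inf)
}

# sens/spec at each candidate cutoff (test-positive: score >= cutoff)
.roc_points <- function(pos, neg, cand) {
  sp <- sort(pos); sn <- sort(neg)
  sens <- (length(pos) - findInterval(cand, sp)) / length(pos)
  spec <- findInterval(cand, sn) / length(neg)
  sens[1] <- 1; spec[1] <- 0             # -Inf sentinel
  sens[length(cand)] <- 0; spec[length(cand)] <- 1
  list(cand = cand, sens = sens, spec = spec)
}

# Mann-Whitney placement values ("structural components"): for each
# positive, the fraction of negatives it beats (ties count 1/2), and vice
# versa. Computed with midranks, O(n log n). mean(v10) == mean(v01) == AUC.
.delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve and Mann-Whitney AUC
#'
#' Builds the empirical ROC of a continuous marker against the
#' fluid-responder label. The AUC is the Mann-Whitney pair statistic:
#' the proportion of (responder, non-responder) pairs ranked correctly,
#' ties counting one half. Pairs with a missing score or label are dropped.
#'
#' @param scores Marker values.
#' @param labels Logical (or coercible) responder labels.
#' @param direction `"higher"` if larger marker values indicate a
#'   responder (the default; all LRM-change markers behave this way),
#'   `"lower"` for the opposite orientation.
#' @return An object of class `roc_result`: list with `thresholds`
#'   (candidate cutoffs, rising), `sens`, `spec`, `auc`, `direction`,
#'   `n_pos`, `n_neg`, `n_dropped`, and the cleaned `scores`/`labels`.
#' @export
#' @examples
#' empirical_roc(c(3, 5, 7, 1, 2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc
empirical_roc <- function(scores, labels, direction = "higher") {
  direction <- .roc_direction(direction)
  cp <- clean_pairs(scores, labels)
  if (!any(cp$labels) || all(cp$labels))
    stop("degenerate input: need at least one responder and one non-responder")
  s <- .orient(cp$scores, direction)
  pos <- s[cp$labels]; neg <- s[!cp$labels]
  pts <- .roc_points(pos, neg, .roc_candidates(s))
  auc <- .delong_components(pos, neg)$auc
  thr <- if (direction == "lower") rev(-pts$cand) else pts$cand
  sens <- if (direction == "lower") rev(pts$sens) else pts$sens
  spec <- if (direction == "lower") rev(pts$spec) else pts$spec
  structure(list(thresholds = thr, sens = sens, spec = spec, auc = auc,
                 auc_ci = NULL, direction = direction,
                 n_pos = length(pos), n_neg = length(neg),
                 n_dropped = cp$n_dropped,
                 scores = cp$scores, labels = cp$labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.3f (%d responders, %d non-responders, direction = %s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  if (!is.null(x$auc_ci))
    cat(sprintf("  95%% CI (DeLong): %.3f-%.3f\n", x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation CI using the DeLong structural-components variance
#' `var(V10)/m + var(V01)/n`, truncated to `[0, 1]`. With perfectly
#' separated groups the variance is zero and the interval collapses to the
#' point estimate.
#'
#' @param roc A `roc_result` from [empirical_roc()].
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
delong_ci <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_result"))
  if (roc$n_pos < 2 || roc$n_neg < 2)
    stop("variance-undefined: need at least 2 responders and 2 non-responders")
  s <- .orient(roc$scores, roc$direction)
  comp <- .delong_components(s[roc$labels], s[!roc$labels])
  se <- sqrt(stats::var(comp$v10) / roc$n_pos +
             stats::var(comp$v01) / roc$n_neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, roc$auc - z * se), min(1, roc$auc + z * se))
}

#' Paired DeLong test comparing two AUCs
#'
#' Compares two markers measured on the same patients. Patients missing
#' either marker (or the label) are dropped, so both AUCs are computed on
#' the common subset. The two-sided p-value comes from the normal
#' approximation to the paired AUC difference, whose variance uses the
#' covariance of the DeLong structural components.
#'
#' @param scores_a,scores_b The two markers.
#' @param labels Responder labels.
#' @param direction_a,direction_b Orientation of each marker.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `n_pos`, `n_neg`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               direction_a = "higher",
                               direction_b = "higher") {
  direction_a <- .roc_direction(direction_a)
  direction_b <- .roc_direction(direction_b)
  labels <- as.logical(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  a <- .orient(scores_a[keep], direction_a)
  b <- .orient(scores_b[keep], direction_b)
  lab <- labels[keep]
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least 2 complete pairs per class")
  ca <- .delong_components(a[lab], a[!lab])
  cb <- .delong_components(b[lab], b[!lab])
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  v <- stats::var(d10) / sum(lab) + stats::var(d01) / sum(!lab)
  diff <- ca$auc - cb$auc
  z <- if (v <= .Machine$double.eps) {
    if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else diff / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), n_pos = sum(lab), n_neg = sum(!lab))
}

#' Youden-index optimal cutoff
#'
#' Evaluates J = Sn + Sp - 1 at every attainable cutoff (midpoints between
#' adjacent distinct observed values plus the infinite sentinels) and
#' returns the maximizer. Ties are broken toward higher sensitivity: with
#' `direction = "higher"` the smallest maximizing cutoff is reported.
#'
#' @inheritParams empirical_roc
#' @return An object of class `cutoff_result`: list with `cutoff`
#'   (test-positive means `score >= cutoff` for `"higher"`), `youden_j`,
#'   `sens`, `spec`, `direction`.
#' @export
youden_best_cutoff <- function(scores, labels, direction = "higher") {
  direction <- .roc_direction(direction)
  cp <- clean_pairs(scores, labels)
  if (!any(cp$labels) || all(cp$labels))
    stop("degenerate input: need at least one responder and one non-responder")
  s <- .orient(cp$scores, direction)
  pts <- .roc_points(s[cp$labels], s[!cp$labels], .roc_candidates(s))
  j <- pts$sens + pts$spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]   # smallest oriented cutoff wins ties
  cutoff <- pts$cand[best]
  if (direction == "lower") cutoff <- -cutoff
  structure(list(cutoff = cutoff, youden_j = j[best],
                 sens = pts$sens[best], spec = pts$spec[best],
                 direction = direction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  op <- if (x$direction == "higher") ">=" else "<="
  cat(sprintf("Youden-best cutoff: score %s %.4g (J = %.3f, Sn = %.3f, Sp = %.3f)\n",
              op, x$cutoff, x$youden_j, x$sens, x$spec))
  invisible(x)
}
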