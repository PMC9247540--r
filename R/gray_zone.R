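# Gray-zone (inconclusive-interval) construction for a diagnostic marker:
# (1) percentile bootstrap of the Youden-optimal cutoff, and (2) the
# triadic rule-out / inconclusive / rule-in partition from sensitivity and
# specificity floors. The wider of the two is the reported gray zone.

.gray_zone_obj <- function(lower, upper, method, scores, extras = list()) {
  scores <- scores[!is.na(scores)]
  below <- mean(scores < lower)
  inside <- mean(scores >= lower & scores <= upper)  # closed interval
  above <- mean(scores > upper)
  structure(c(list(lower = lower, upper = upper, method = method,
                   fractions = c(below = below, inside = inside,
                                 above = above),
                   n = length(scores)), extras),
            class = "gray_zone")
}

#' @export
print.gray_zone <- function(x, ...) {
  cat(sprintf("Gray zone (%s): %.4g to %.4g\n", x$method, x$lower, x$upper))
  f <- round_half_up(100 * x$fractions, 1)
  cat(sprintf("  below (rule-out): %s%%  inside (inconclusive): %s%%  above (rule-in): %s%%\n",
              format(f[1]), format(f[2]), format(f[3])))
  invisible(x)
}

#' Bootstrap gray zone of the optimal cutoff
#'
#' Resamples patients with replacement (whole-cohort, non-stratified by
#' default), recomputes the Youden-best cutoff on each replicate, and takes
#' the percentile interval of the replicate cutoffs as the gray zone.
#' Replicates that draw a single class are redrawn (and counted), so
#' exactly `n_boot` cutoffs enter the percentiles.
#'
#' @inheritParams empirical_roc
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param level Level of the percentile interval (default 0.95).
#' @param seed Optional integer seed; the caller's RNG stream is restored.
#' @param stratified Resample within each class instead (default `FALSE`).
#' @return A `gray_zone` object (`method = "bootstrap"`), with the
#'   replicate cutoffs in `$boot_cutoffs` and the redraw count in
#'   `$n_redrawn`.
#' @export
bootstrap_cutoff_zone <- function(scores, labels, n_boot = 1000,
                                  level = 0.95, seed = NULL,
                                  direction = "higher", stratified = FALSE) {
  direction <- .roc_direction(direction)
  if (n_boot < 100) stop("n_boot must be >= 100")
  cp <- clean_pairs(scores, labels)
  if (!any(cp$labels) || all(cp$labels))
    stop("degenerate input: need at least one responder and one non-responder")
  n <- length(cp$scores)
  idx_pos <- which(cp$labels); idx_neg <- which(!cp$labels)
  with_seed(seed, {
    cuts <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- if (stratified)
          c(sample(idx_pos, length(idx_pos), replace = TRUE),
            sample(idx_neg, length(idx_neg), replace = TRUE))
        else sample.int(n, n, replace = TRUE)
        lab <- cp$labels[idx]
        if (any(lab) && !all(lab)) break
        n_redrawn <- n_redrawn + 1L
      }
      cuts[b] <- youden_best_cutoff(cp$scores[idx], lab, direction)$cutoff
    }
    if (n_redrawn > 0)
      message(n_redrawn, " single-class bootstrap replicate(s) redrawn")
    alpha <- 1 - level
    q <- stats::quantile(cuts, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    .gray_zone_obj(q[1], q[2], "bootstrap", cp$scores,
                   extras = list(boot_cutoffs = cuts, n_boot = n_boot,
                                 n_redrawn = n_redrawn, level = level))
  })
}

#' Triadic gray zone from sensitivity/specificity floors
#'
#' Partitions the marker range into rule-out, inconclusive and rule-in
#' regions. With `direction = "higher"`: the lower bound is the largest
#' candidate cutoff whose sensitivity is still at least `sn_floor` (below
#' it a negative test safely rules out responsiveness); the upper bound is
#' the smallest candidate cutoff whose specificity reaches `sp_floor`
#' (above it a positive test rules it in). If the bounds cross, the zone
#' is empty and collapses to their midpoint.
#'
#' @inheritParams empirical_roc
#' @param sn_floor,sp_floor Sensitivity and specificity floors
#'   (default 0.90 each).
#' @return A `gray_zone` object (`method = "triadic"`).
#' @export
triadic_zone <- function(scores, labels, sn_floor = 0.90, sp_floor = 0.90,
                         direction = "higher") {
  direction <- .roc_direction(direction)
  cp <- clean_pairs(scores, labels)
  if (!any(cp$labels) || all(cp$labels))
    stop("degenerate input: need at least one responder and one non-responder")
  s <- .orient(cp$scores, direction)
  pts <- .roc_points(s[cp$labels], s[!cp$labels], .roc_candidates(s))
  lower <- max(pts$cand[pts$sens >= sn_floor - 1e-12])
  upper <- min(pts$cand[pts$spec >= sp_floor - 1e-12])
  if (lower > upper) {
    mid <- if (is.finite(lower) && is.finite(upper)) (lower + upper) / 2
           else stats::median(s)
    lower <- upper <- mid
  }
  if (direction == "lower") {
    tmp <- lower; lower <- -upper; upper <- -tmp
  }
  .gray_zone_obj(lower, upper, "triadic", cp$scores,
                 extras = list(sn_floor = sn_floor, sp_floor = sp_floor))
}

#' Combined (two-approach) gray zone
#'
#' Computes both the bootstrap and the triadic zone and reports whichever
#' is wider; on an exact width tie the triadic zone is preferred. The
#' population fractions below / inside / above are computed on the analysis
#' cohort.
#'
#' @inheritParams bootstrap_cutoff_zone
#' @inheritParams triadic_zone
#' @return A `gray_zone` object (`method = "combined"`), carrying both
#'   component zones as `$bootstrap` and `$triadic` and the name of the
#'   winner as `$chosen`.
#' @export
combined_zone <- function(scores, labels, n_boot = 1000, level = 0.95,
                          seed = NULL, sn_floor = 0.90, sp_floor = 0.90,
                          direction = "higher", stratified = FALSE) {
  bz <- bootstrap_cutoff_zone(scores, labels, n_boot = n_boot, level = level,
                              seed = seed, direction = direction,
                              stratified = stratified)
  tz <- triadic_zone(scores, labels, sn_floor = sn_floor,
                     sp_floor = sp_floor, direction = direction)
  bw <- bz$upper - bz$lower
  tw <- tz$upper - tz$lower
  win <- if (bw > tw) bz else tz        # ties go to the triadic zone
  cp <- clean_pairs(scores, labels)
  .gray_zone_obj(win$lower, win$upper, "combined", cp$scores,
                 extras = list(bootstrap = bz, triadic = tz,
                               chosen = win$method))
}
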