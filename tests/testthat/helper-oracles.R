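# Independent brute-force oracles used to check the fast implementations.

# O(n^2) Mann-Whitney pair counting: concordant pairs + half ties
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exhaustive Youden search over all midpoint cutoffs (score >= c positive)
youden_exhaustive_oracle <- function(scores, labels) {
  v <- sort(unique(scores))
  cand <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  best <- list(j = -Inf, cutoff = NA)
  for (c0 in cand) {
    sn <- mean(scores[labels] >= c0)
    sp <- mean(scores[!labels] < c0)
    j <- sn + sp - 1
    if (j > best$j + 1e-12) best <- list(j = j, cutoff = c0, sens = sn, spec = sp)
  }
  best
}

# Clopper-Pearson by direct root finding on the binomial tails
cp_root_oracle <- function(s, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (s == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(s - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (s == n) 1 else
    stats::uniroot(function(p) stats::pbinom(s, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# small hand-built cohort with plausible physiology, n rows
make_tiny_cohort <- function(n = 4, seed = 42) {
  set.seed(seed)
  base <- data.frame(patient_id = sprintf("X%02d", seq_len(n)))
  vals <- list(pi = 2.3, sv = 65, co = 4.5, sbp = 115, dbp = 62, map = 80,
               hr = 72, ppv = 14, svv = 20, pvi = 13)
  for (v in names(vals)) {
    for (tp in c("t1", "t2", "t3", "t4")) {
      mult <- switch(tp, t1 = 1, t2 = 0.7, t3 = 0.98, t4 = 1.1)
      base[[paste0(v, "_", tp)]] <-
        vals[[v]] * mult * exp(stats::rnorm(n, 0, 0.05))
    }
  }
  base
}
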