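# Internal numeric helpers.

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# truncated-normal quantile function: maps p in (0,1) to the
# N(mean, sd) distribution truncated to [lower, upper]
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + p * (pb - pa), mean, sd)
}

rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; NULL seed leaves the stream alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# coerce labels to logical (responder = TRUE) and pair with scores,
# dropping incomplete pairs
clean_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  list(scores = scores[keep], labels = labels[keep],
       n_dropped = sum(!keep))
}
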