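# ROC sample-size calculation (Obuchowski's binormal method) and dropout
# inflation.

#' Binormal variance function for an AUC
#'
#' `V(A) = 0.0099 * exp(-a^2/2) * ((5 a^2 + 8) + (a^2 + 8)/R)` with
#' `a = sqrt(2) * qnorm(A)` and `R` negatives per positive; the
#' equal-variance binormal form used for ROC sample-size planning. At the
#' null `A = 0.5` this reduces to `0.0099 * (8 + 8/R)` exactly.
#'
#' @param auc Area under the curve, in `[0.5, 1)`.
#' @param ratio Negatives per positive (R > 0).
#' @return The variance of the AUC estimator per positive subject.
#' @export
obuchowski_variance <- function(auc, ratio) {
  stopifnot(auc >= 0.5, auc < 1, ratio > 0)
  a <- sqrt(2) * stats::qnorm(auc)
  0.0099 * exp(-a^2 / 2) * ((5 * a^2 + 8) + (a^2 + 8) / ratio)
}

#' ROC sample size (Obuchowski's method)
#'
#' Number of patients needed to show that a marker's AUC exceeds a null
#' value. The positive-group size is
#' `n_pos = (z_alpha * sqrt(V(auc_null)) + z_power * sqrt(V(auc_alt)))^2 /
#' (auc_alt - auc_null)^2` with the binormal variance function
#' [obuchowski_variance()]; the total is `n_pos * (1 + R)` rounded half-up
#' before the group sizes are re-derived from the stated ratio.
#'
#' @param auc_alt Alternative-hypothesis AUC (`auc_null < auc_alt < 1`).
#' @param auc_null Null AUC (default 0.5).
#' @param ratio Negatives per positive (default 1).
#' @param alpha Type-I error (default 0.05).
#' @param power Target power (default 0.90).
#' @param sided `"one"` (default; the directional alternative AUC > null)
#'   or `"two"`.
#' @return List with `n_pos`, `n_neg`, `n_total`, and the unrounded
#'   `n_pos_raw`.
#' @export
#' @examples
#' obuchowski_n(0.80, 0.50, ratio = 1.222)$n_total # 27
obuchowski_n <- function(auc_alt, auc_null = 0.5, ratio = 1,
                         alpha = 0.05, power = 0.90,
                         sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    stop("validation error: need 0.5 <= auc_null < auc_alt < 1")
  if (ratio <= 0) stop("validation error: ratio must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("validation error: alpha and power must be in (0, 1)")
  z_a <- stats::qnorm(1 - alpha / if (sided == "two") 2 else 1)
  z_b <- stats::qnorm(power)
  v0 <- obuchowski_variance(auc_null, ratio)
  va <- obuchowski_variance(auc_alt, ratio)
  n_pos_raw <- (z_a * sqrt(v0) + z_b * sqrt(va))^2 / (auc_alt - auc_null)^2
  n_total <- round_half_up(n_pos_raw * (1 + ratio))
  n_pos <- round_half_up(n_total / (1 + ratio))
  list(n_pos = as.integer(n_pos), n_neg = as.integer(n_total - n_pos),
       n_total = as.integer(n_total), n_pos_raw = n_pos_raw)
}

#' Inflate a sample size for expected dropout
#'
#' @param n Required evaluable patients.
#' @param dropout Expected dropout proportion, in `[0, 1)`.
#' @return `ceiling(n / (1 - dropout))`.
#' @export
#' @examples
#' inflate_for_dropout(27, 0.15) # 32
inflate_for_dropout <- function(n, dropout) {
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)")
  as.integer(ceiling(n / (1 - dropout)))
}
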