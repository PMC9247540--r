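# Relative-change statistics around the LRM and VE challenges, and the
# >= 10% stroke-volume rule that defines a fluid responder.

#' Relative percent decrease
#'
#' `(before - after) / before * 100`: positive when the value fell during the
#' intervention. This is the sign convention used for PI, SV, CO, pressures
#' and HR across the lung recruitment maneuver.
#'
#' @param before Pre-intervention value(s); must be strictly positive.
#' @param after Post-intervention value(s).
#' @return Percent decrease (vectorized); `NA` where either input is `NA`.
#' @export
#' @examples
#' relative_decrease(2.5, 1.5) # 40
relative_decrease <- function(before, after) {
  if (any(!is.na(before) & before <= 0))
    stop("domain error: 'before' must be > 0")
  (before - after) / before * 100
}

#' Relative percent increase
#'
#' `(after - before) / before * 100`: positive when the value rose. Used for
#' the respiratory-variation indices (PPV, SVV, PVI) across the recruitment
#' maneuver and for all changes across volume expansion.
#'
#' @inheritParams relative_decrease
#' @return Percent increase (vectorized); `NA` where either input is `NA`.
#' @export
#' @examples
#' relative_increase(10, 15) # 50
relative_increase <- function(before, after) {
  if (any(!is.na(before) & before <= 0))
    stop("domain error: 'before' must be > 0")
  (after - before) / before * 100
}

#' Derive per-patient change statistics and the responder label
#'
#' Computes the full change set from a cohort table: decrease-form changes
#' over T1 -> T2 for PI, SV, CO, SBP, DBP, MAP and HR; increase-form changes
#' over T1 -> T2 for PPV, SVV and PVI; increase-form changes over T3 -> T4
#' for SV, CO and MAP. A change is missing iff one of its two inputs is
#' missing. The responder label is `delta_sv_ve >= threshold` (missing when
#' `delta_sv_ve` is).
#'
#' @param cohort A cohort data frame ([read_cohort()], [generate_cohort()]).
#' @param threshold Responder threshold on `delta_sv_ve`, percent
#'   (default 10).
#' @return A data frame with `patient_id`, the thirteen `delta_*` columns
#'   (percent), and logical `responder`.
#' @export
derive_changes <- function(cohort, threshold = 10) {
  validate_cohort(cohort)
  dec_vars <- c("pi", "sv", "co", "sbp", "dbp", "map", "hr")
  inc_vars <- c("ppv", "svv", "pvi")
  out <- data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE)
  for (v in dec_vars)
    out[[paste0("delta_", v, "_lrm")]] <-
      relative_decrease(cohort[[paste0(v, "_t1")]], cohort[[paste0(v, "_t2")]])
  for (v in inc_vars)
    out[[paste0("delta_", v, "_lrm")]] <-
      relative_increase(cohort[[paste0(v, "_t1")]], cohort[[paste0(v, "_t2")]])
  for (v in c("sv", "co", "map"))
    out[[paste0("delta_", v, "_ve")]] <-
      relative_increase(cohort[[paste0(v, "_t3")]], cohort[[paste0(v, "_t4")]])
  out$responder <- out$delta_sv_ve >= threshold
  out
}

#' Classify a patient as fluid responder
#'
#' A patient is a fluid responder when stroke volume rises by at least
#' `threshold` percent (default 10, boundary inclusive) after volume
#' expansion.
#'
#' @param delta_sv_ve Percent change in SV across VE; must be present.
#' @param threshold Responder threshold, percent.
#' @return Logical vector.
#' @export
#' @examples
#' classify_responder(c(10, 9.99, 22.07)) # TRUE FALSE TRUE
classify_responder <- function(delta_sv_ve, threshold = 10) {
  if (any(is.na(delta_sv_ve)))
    stop("classification error: delta_sv_ve is missing")
  delta_sv_ve >= threshold
}

#' Check return to baseline
#'
#' Between the recruitment maneuver and the fluid challenge, measurements
#' must return to their first baseline: the absolute relative deviation from
#' the reference must be strictly below `tolerance` percent (exactly 10% is
#' a failure).
#'
#' @param reference Baseline value(s); must be strictly positive.
#' @param current Current value(s).
#' @param tolerance Allowed deviation, percent (default 10).
#' @return Logical vector; `NA` where either input is `NA`.
#' @export
#' @examples
#' baseline_return_check(60, 65) # TRUE (8.3%)
#' baseline_return_check(60, 66) # FALSE (exactly 10%)
baseline_return_check <- function(reference, current, tolerance = 10) {
  if (any(!is.na(reference) & reference <= 0))
    stop("domain error: 'reference' must be > 0")
  abs(current - reference) / reference * 100 < tolerance
}
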