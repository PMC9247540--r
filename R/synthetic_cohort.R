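# Synthetic-cohort generator. Emulates a perioperative cohort measured at
# four time points around a lung recruitment maneuver (T1/T2) and a volume
# expansion (T3/T4), calibrated to published group-wise summary statistics
# (fluid responders vs non-responders).
#
# All marginals are truncated normal. Parent parameters are moment-matched
# so the *truncated* distribution has exactly the requested mean/SD; the
# only explicitly correlated pair is (delta_pi_lrm, delta_sv_lrm), linked by
# a Gaussian copula within group.

# truncation bounds, percent scale
.lrm_dec_bounds <- c(-50, 100)   # relative decreases during LRM
.lrm_inc_bounds <- c(-90, 500)   # relative increases during LRM
.ve_bounds      <- c(-50, 200)   # relative changes across VE
.ve_sv_resp_lb  <- 10            # responders' SV change is >= 10 by definition
.t3_drift_sd    <- 4             # % drift of T3 around T1
.t3_drift_bound <- 9.5           # strictly inside the <10% baseline-return rule

# mean/sd of a normal(mu, sigma) truncated to [a, b]
.tn_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  phi_a <- stats::dnorm(al); phi_b <- stats::dnorm(be)
  t1 <- (phi_a - phi_b) / z
  a_term <- if (is.finite(al)) al * phi_a else 0
  b_term <- if (is.finite(be)) be * phi_b else 0
  v <- sigma^2 * (1 + (a_term - b_term) / z - t1^2)
  c(mean = mu + sigma * t1, sd = sqrt(max(v, 0)))
}

.tn_match_cache <- new.env(parent = emptyenv())

# find parent (mu, sigma) whose [a, b]-truncated moments are (m, s)
.tn_match <- function(m, s, a, b) {
  # truncation numerically irrelevant at (m, s): use them directly
  if (stats::pnorm(a, m, s) < 1e-12 && stats::pnorm(b, m, s) > 1 - 1e-12)
    return(c(mu = m, sigma = s))
  key <- paste(m, s, a, b, sep = "|")
  hit <- .tn_match_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mom <- .tn_moments(par[1], exp(par[2]), a, b)
    (mom[1] - m)^2 / s^2 + (mom[2] - s)^2 / s^2
  }
  starts <- list(c(m, log(s)))
  for (k in c(1, 2, 4)) {
    starts <- c(starts, list(c(m - k * s, log(s * (1 + k))),
                             c(m + k * s, log(s * (1 + k)))))
  }
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-16) break
  }
  if (best$value > 1e-8)
    stop(sprintf("cannot match truncated-normal moments (%.3g, %.3g) on [%g, %g]",
                 m, s, a, b))
  res <- c(mu = best$par[1], sigma = exp(best$par[2]))
  .tn_match_cache[[key]] <- res
  res
}

# truncated-normal quantile with parent parameters moment-matched to (m, s)
.q_matched <- function(p, m, s, a, b) {
  par <- .tn_match(m, s, a, b)
  qtruncnorm(p, par["mu"], par["sigma"], a, b)
}

#' Group-wise effect defaults
#'
#' The generator's stated world: baseline (T1) means/SDs, LRM relative
#' changes, VE relative changes, and after-VE variation-index levels, per
#' group (fluid responders vs non-responders). Defaults are the published
#' cohort summaries; values without a published SD (the SVV change during
#' LRM, the VE-change SDs, and the T4 drift of PI/pressures/HR) are fixed
#' realistic choices documented in the methods vignette.
#'
#' @return A list of four data frames: `baseline` (T1 levels, all ten
#'   variables), `lrm_change` (percent change T1 to T2; `form` says whether
#'   the decrease or increase convention applies), `ve_change` (percent
#'   increase T3 to T4), and `ve_direct` (T4 levels of PPV/SVV/PVI, which
#'   have no T3 measurement). Columns: `resp_mean`, `resp_sd`,
#'   `nonresp_mean`, `nonresp_sd`.
#' @export
default_group_effects <- function() {
  baseline <- data.frame(
    variable     = c("pi", "sv", "co", "sbp", "dbp", "map", "hr",
                     "ppv", "svv", "pvi"),
    resp_mean    = c(2.30, 60.3, 4.28, 113, 64, 82, 75, 18.85, 25.91, 13.92),
    resp_sd      = c(1.98, 25.4, 1.30, 18, 17, 16, 17, 7.55, 12.56, 4.77),
    nonresp_mean = c(2.35, 77.7, 5.13, 114, 61, 81, 67, 9.53, 17.88, 12.00),
    nonresp_sd   = c(2.08, 21.4, 1.69, 18, 8, 13, 14, 6.00, 6.28, 6.82)
  )
  lrm_change <- data.frame(
    variable     = c("pi", "sv", "co", "sbp", "dbp", "map", "hr",
                     "ppv", "svv", "pvi"),
    form         = c(rep("decrease", 7), rep("increase", 3)),
    resp_mean    = c(55.23, 49.42, 58.92, 30.42, 19.12, 26.27, 5.08,
                     58.1, 71.8, 45.3),
    resp_sd      = c(17.82, 21.49, 18.70, 11.56, 10.59, 10.93, 8.93,
                     84.8, 60, 10.0),
    nonresp_mean = c(35.32, 39.79, 47.39, 20.22, 14.55, 19.47, 7.12,
                     95.9, 52.5, 35.9),
    nonresp_sd   = c(17.32, 21.44, 22.87, 10.50, 8.99, 9.61, 7.50,
                     102.5, 60, 6.4)
  )
  ve_change <- data.frame(
    variable     = c("sv", "co", "map", "pi", "sbp", "dbp", "hr"),
    resp_mean    = c(22.07, 18.82, 3.75, 12.0, 7.41, 0, -2.67),
    resp_sd      = c(10, 10, 10, 10, 10, 10, 10),
    nonresp_mean = c(0.26, 2.48, 14.29, -13.69, 14.02, 13.79, 1.56),
    nonresp_sd   = c(4, 10, 10, 10, 10, 10, 10)
  )
  ve_direct <- data.frame(
    variable     = c("ppv", "svv", "pvi"),
    resp_mean    = c(12.0, 18.4, 9.7),
    resp_sd      = c(8.2, 8.0, 3.2),
    nonresp_mean = c(6.0, 18.8, 12.6),
    nonresp_sd   = c(3.5, 12.2, 6.5)
  )
  list(baseline = baseline, lrm_change = lrm_change,
       ve_change = ve_change, ve_direct = ve_direct)
}

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients (>= 2).
#' @param responder_fraction Probability a patient is drawn as a fluid
#'   responder (default 0.406, the published prevalence 13/32).
#' @param rho_pi_sv Within-group Gaussian-copula correlation between the PI
#'   and SV relative decreases during LRM (default 0.35, which yields a
#'   pooled r-squared of about 0.16 given the default group effects).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param effects Group-wise effect tables, see [default_group_effects()].
#' @param svv_missing_nonresponders Number of non-responders whose SVV is
#'   blanked at all time points (device dropout; default 0).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 32, responder_fraction = 0.406,
                        rho_pi_sv = 0.35, seed = 1L,
                        effects = default_group_effects(),
                        svv_missing_nonresponders = 0L) {
  stopifnot(n_patients >= 2, length(seed) == 1L)
  if (responder_fraction <= 0 || responder_fraction >= 1)
    stop("validation error: responder_fraction must be in (0, 1)")
  if (abs(rho_pi_sv) >= 1)
    stop("validation error: |rho_pi_sv| must be < 1")
  for (tab in effects) {
    if (any(tab$resp_sd < 0) || any(tab$nonresp_sd < 0))
      stop("validation error: effect SDs must be >= 0")
  }
  if (any(effects$baseline$resp_mean <= 0) ||
      any(effects$baseline$nonresp_mean <= 0))
    stop("validation error: baseline means must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 responder_fraction = responder_fraction,
                 rho_pi_sv = rho_pi_sv, seed = as.integer(seed),
                 effects = effects,
                 svv_missing_nonresponders =
                   as.integer(svv_missing_nonresponders)),
            class = "cohort_spec")
}

#' The published-cohort default spec
#'
#' A 32-patient cohort with responder fraction 0.406 and the published
#' group-wise means/SDs, including two non-responders with missing SVV
#' (matching the published N = 17 for that variable).
#'
#' @param n_patients Cohort size (default 32).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
paper_default_spec <- function(n_patients = 32, seed = 1L) {
  cohort_spec(n_patients = n_patients, seed = seed,
              svv_missing_nonresponders = if (n_patients >= 32) 2L else 0L)
}

# group-wise draw through the matched truncated-normal quantile
.draw_grouped <- function(u, group, m_r, s_r, m_n, s_n, a, b) {
  out <- numeric(length(u))
  if (any(group))  out[group]  <- .q_matched(u[group],  m_r, s_r, a, b)
  if (any(!group)) out[!group] <- .q_matched(u[!group], m_n, s_n, a, b)
  out
}

.pressure_vars <- c("sbp", "dbp", "map")

#' Generate a synthetic cohort
#'
#' Deterministic given the spec's seed. Stream order: (1) group membership;
#' (2) T1 baselines, variable by variable in schema order, the three
#' arterial pressures sharing one latent uniform per patient; (3) T3 drift
#' for the seven non-variation variables (pressures again share one draw);
#' (4) LRM relative changes -- one bivariate normal pair for (PI, SV), then
#' the remaining variables in schema order with a shared draw for the
#' pressure changes; (5) VE relative changes (SV, CO, pressures, PI, HR);
#' (6) after-VE PPV/SVV/PVI levels; (7) SVV missingness. T2 and T4 panels
#' are computed from the baselines and the drawn relative changes, and MAP
#' is clamped into `[DBP, SBP]` at each time point (a rare ~1e-4 repair
#' that keeps the pressure-ordering invariant). The responder label is
#' *re-derived* from the realized `delta_sv_ve`, so a non-responder drawn
#' above the 10% boundary is relabeled (the drawn group is kept in
#' `attr(cohort, "drawn_responder")`).
#'
#' @param spec A [cohort_spec()].
#' @return A cohort data frame (see [cohort_schema()]) with attribute
#'   `drawn_responder` (logical, the group each patient was simulated from).
#' @export
#' @examples
#' cohort <- generate_cohort(paper_default_spec(seed = 7))
#' table(derive_changes(cohort)$responder)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  eff <- spec$effects
  n <- spec$n_patients
  with_seed(spec$seed, {
    group <- stats::runif(n) < spec$responder_fraction

    cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                         stringsAsFactors = FALSE)
    # T1 baselines (all strictly positive); SBP/DBP/MAP are comonotone
    # within group so the ordering invariant can hold
    u_press <- NULL
    for (i in seq_len(nrow(eff$baseline))) {
      row <- eff$baseline[i, ]
      if (row$variable %in% .pressure_vars) {
        if (is.null(u_press)) u_press <- stats::runif(n)
        u <- u_press
      } else u <- stats::runif(n)
      cohort[[paste0(row$variable, "_t1")]] <-
        .draw_grouped(u, group, row$resp_mean, row$resp_sd,
                      row$nonresp_mean, row$nonresp_sd, 0, Inf)
    }
    # T3 baselines: drift around T1, strictly inside the <10% return rule
    u_press_drift <- NULL
    for (v in c("pi", "sv", "co", "sbp", "dbp", "map", "hr")) {
      if (v %in% .pressure_vars) {
        if (is.null(u_press_drift)) u_press_drift <- stats::runif(n)
        u <- u_press_drift
      } else u <- stats::runif(n)
      drift <- qtruncnorm(u, 0, .t3_drift_sd,
                          -.t3_drift_bound, .t3_drift_bound)
      cohort[[paste0(v, "_t3")]] <- cohort[[paste0(v, "_t1")]] * (1 + drift / 100)
    }
    for (v in c("ppv", "svv", "pvi")) cohort[[paste0(v, "_t3")]] <- NA_real_

    # LRM changes: correlated (PI, SV) pair first, via a Gaussian copula
    z1 <- stats::rnorm(n)
    z2 <- spec$rho_pi_sv * z1 + sqrt(1 - spec$rho_pi_sv^2) * stats::rnorm(n)
    lrm <- list()
    pi_row <- eff$lrm_change[eff$lrm_change$variable == "pi", ]
    sv_row <- eff$lrm_change[eff$lrm_change$variable == "sv", ]
    lrm$pi <- .draw_grouped(stats::pnorm(z1), group,
                            pi_row$resp_mean, pi_row$resp_sd,
                            pi_row$nonresp_mean, pi_row$nonresp_sd,
                            .lrm_dec_bounds[1], .lrm_dec_bounds[2])
    lrm$sv <- .draw_grouped(stats::pnorm(z2), group,
                            sv_row$resp_mean, sv_row$resp_sd,
                            sv_row$nonresp_mean, sv_row$nonresp_sd,
                            .lrm_dec_bounds[1], .lrm_dec_bounds[2])
    u_press_lrm <- NULL
    for (i in seq_len(nrow(eff$lrm_change))) {
      row <- eff$lrm_change[i, ]
      if (row$variable %in% c("pi", "sv")) next
      if (row$variable %in% .pressure_vars) {
        if (is.null(u_press_lrm)) u_press_lrm <- stats::runif(n)
        u <- u_press_lrm
      } else u <- stats::runif(n)
      b <- if (row$form == "decrease") .lrm_dec_bounds else .lrm_inc_bounds
      lrm[[row$variable]] <-
        .draw_grouped(u, group, row$resp_mean, row$resp_sd,
                      row$nonresp_mean, row$nonresp_sd, b[1], b[2])
    }
    for (i in seq_len(nrow(eff$lrm_change))) {
      row <- eff$lrm_change[i, ]
      t1 <- cohort[[paste0(row$variable, "_t1")]]
      delta <- lrm[[row$variable]]
      cohort[[paste0(row$variable, "_t2")]] <-
        if (row$form == "decrease") t1 * (1 - delta / 100)
        else t1 * (1 + delta / 100)
    }

    # VE changes (increase form, T3 -> T4); responders' SV change is drawn
    # at or above the 10% boundary, non-responders may cross it
    u_press_ve <- NULL
    for (i in seq_len(nrow(eff$ve_change))) {
      row <- eff$ve_change[i, ]
      if (row$variable %in% .pressure_vars) {
        if (is.null(u_press_ve)) u_press_ve <- stats::runif(n)
        u <- u_press_ve
      } else u <- stats::runif(n)
      delta <- numeric(n)
      lb_resp <- if (row$variable == "sv") .ve_sv_resp_lb else .ve_bounds[1]
      if (any(group))
        delta[group] <- .q_matched(u[group], row$resp_mean, row$resp_sd,
                                   lb_resp, .ve_bounds[2])
      if (any(!group))
        delta[!group] <- .q_matched(u[!group], row$nonresp_mean,
                                    row$nonresp_sd,
                                    .ve_bounds[1], .ve_bounds[2])
      cohort[[paste0(row$variable, "_t4")]] <-
        cohort[[paste0(row$variable, "_t3")]] * (1 + delta / 100)
    }
    # variation indices after VE (no T3 value exists)
    for (i in seq_len(nrow(eff$ve_direct))) {
      row <- eff$ve_direct[i, ]
      cohort[[paste0(row$variable, "_t4")]] <-
        .draw_grouped(stats::runif(n), group, row$resp_mean, row$resp_sd,
                      row$nonresp_mean, row$nonresp_sd, 0, Inf)
    }

    # device dropout: blank SVV entirely for some non-responders
    k <- min(spec$svv_missing_nonresponders, sum(!group))
    if (k > 0) {
      idx <- sample(which(!group), k)
      for (tp in c("t1", "t2", "t3", "t4"))
        cohort[[paste0("svv_", tp)]][idx] <- NA_real_
    }

    # keep MAP inside [DBP, SBP] (comonotonicity makes violations ~1e-4)
    for (tp in c("t1", "t2", "t3", "t4")) {
      sbp <- cohort[[paste0("sbp_", tp)]]
      dbp <- cohort[[paste0("dbp_", tp)]]
      map <- cohort[[paste0("map_", tp)]]
      cohort[[paste0("map_", tp)]] <- pmin(pmax(map, dbp), sbp)
    }

    cohort <- cohort[c("patient_id", .measure_cols())]
    attr(cohort, "drawn_responder") <- group
    validate_cohort(cohort)
    cohort
  })
}
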