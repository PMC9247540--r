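# End-to-end pipeline: cohort -> changes -> responder label -> group/time
# comparisons -> ROC table -> cutoff metrics -> gray zone -> correlation /
# concordance -> sample-size echo. Every stochastic stage takes its seed
# from the config, so a rerun with the same config is identical.

#' Analysis configuration
#'
#' @param markers Named character vector: marker column (in the table
#'   produced by the pipeline, i.e. a `delta_*` change or a `<var>_t1`
#'   baseline) -> direction (`"higher"` or `"lower"`). The first marker is
#'   the primary one used for the cutoff block and gray zone.
#' @param responder_threshold Percent SV increase defining a responder
#'   (default 10).
#' @param cutoff_policy `"youden"` (default) or `"fixed"` (then
#'   `fixed_cutoff` applies to the primary marker).
#' @param fixed_cutoff Cutoff used when `cutoff_policy = "fixed"`.
#' @param boot_n,boot_seed,level Bootstrap replicates, seed and CI level
#'   for the gray zone and DeLong intervals.
#' @param sn_floor,sp_floor Triadic gray-zone floors (default 0.90).
#' @param concordance_exclusion Exclusion half-width for the four-quadrant
#'   concordance (default 10%).
#' @param samplesize Arguments echoed through [obuchowski_n()], plus
#'   `dropout`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(markers = c(delta_pi_lrm = "higher",
                                        delta_sv_lrm = "higher",
                                        delta_co_lrm = "higher",
                                        delta_sbp_lrm = "higher",
                                        delta_dbp_lrm = "higher",
                                        delta_map_lrm = "higher",
                                        delta_hr_lrm = "higher",
                                        pvi_t1 = "higher",
                                        ppv_t1 = "higher",
                                        svv_t1 = "higher"),
                            responder_threshold = 10,
                            cutoff_policy = c("youden", "fixed"),
                            fixed_cutoff = NULL,
                            boot_n = 1000, boot_seed = 20201L, level = 0.95,
                            sn_floor = 0.90, sp_floor = 0.90,
                            concordance_exclusion = 10,
                            samplesize = list(auc_alt = 0.80,
                                              auc_null = 0.50,
                                              ratio = 1.222, alpha = 0.05,
                                              power = 0.90, sided = "one",
                                              dropout = 0.15)) {
  cutoff_policy <- match.arg(cutoff_policy)
  if (cutoff_policy == "fixed" && is.null(fixed_cutoff))
    stop("fixed_cutoff required when cutoff_policy = 'fixed'")
  stopifnot(length(markers) >= 1, all(markers %in% c("higher", "lower")),
            boot_seed == as.integer(boot_seed))
  structure(list(markers = markers,
                 responder_threshold = responder_threshold,
                 cutoff_policy = cutoff_policy, fixed_cutoff = fixed_cutoff,
                 boot_n = boot_n, boot_seed = as.integer(boot_seed),
                 level = level, sn_floor = sn_floor, sp_floor = sp_floor,
                 concordance_exclusion = concordance_exclusion,
                 samplesize = samplesize),
            class = "analysis_config")
}

# per-marker analysis table rows (group summaries + AUC with CI)
.marker_table <- function(values, labels, markers, level) {
  rows <- lapply(names(markers), function(mk) {
    x <- values[[mk]]
    resp <- x[labels]; nonresp <- x[!labels]
    auc <- ci_lo <- ci_hi <- NA_real_
    note <- ""
    res <- tryCatch({
      roc <- empirical_roc(x, labels, markers[[mk]])
      auc <- roc$auc
      ci <- tryCatch(delong_ci(roc, level), error = function(e) {
        note <<- conditionMessage(e); c(NA_real_, NA_real_)
      })
      list(auc = auc, ci = ci)
    }, error = function(e) {
      note <<- conditionMessage(e)
      list(auc = NA_real_, ci = c(NA_real_, NA_real_))
    })
    data.frame(marker = mk, direction = unname(markers[[mk]]),
               resp_mean = mean(resp, na.rm = TRUE),
               resp_sd = stats::sd(resp, na.rm = TRUE),
               nonresp_mean = mean(nonresp, na.rm = TRUE),
               nonresp_sd = stats::sd(nonresp, na.rm = TRUE),
               auc = res$auc, auc_lo = res$ci[1], auc_hi = res$ci[2],
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Table-2-style paired before/after comparisons per group and intervention
.comparison_table <- function(cohort, labels) {
  out <- list()
  for (v in .hemo_vars) {
    for (grp in c(TRUE, FALSE)) {
      for (iv in list(c("t1", "t2", "lrm"), c("t3", "t4", "ve"))) {
        sel <- !is.na(labels) & labels == grp
        b <- cohort[[paste0(v, "_", iv[1])]][sel]
        a <- cohort[[paste0(v, "_", iv[2])]][sel]
        res <- tryCatch(compare_paired(b, a),
                        error = function(e) list(statistic = NA_real_,
                                                 p = NA_real_,
                                                 test_used = "unavailable",
                                                 n = sum(!is.na(b) & !is.na(a))))
        out[[length(out) + 1L]] <- data.frame(
          variable = v, group = if (grp) "responder" else "non-responder",
          intervention = iv[3],
          before_mean = mean(b, na.rm = TRUE),
          before_sd = stats::sd(b, na.rm = TRUE),
          after_mean = mean(a, na.rm = TRUE),
          after_sd = stats::sd(a, na.rm = TRUE),
          n = res$n, p = res$p, test = res$test_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full diagnostic-evaluation pipeline
#'
#' Derives the change statistics and responder labels, then produces the
#' comparison tables, the per-marker ROC/AUC table, the cutoff metric
#' block with confidence intervals, the two-approach gray zone of the
#' primary marker, the PI/SV correlation and trending concordance, and a
#' sample-size echo. Stage failures are caught, recorded under
#' `$stage_errors`, and do not abort the remaining stages.
#'
#' @param cohort A cohort data frame ([read_cohort()] /
#'   [generate_cohort()]).
#' @param config An [analysis_config()].
#' @return An object of class `fluidroc_report`.
#' @export
#' @examples
#' rep <- run_pipeline(generate_cohort(paper_default_spec(seed = 2)))
#' rep$marker_table[1, c("marker", "auc")]
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  validate_cohort(cohort)
  errors <- list()
  note <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }

  changes <- derive_changes(cohort, config$responder_threshold)
  labels <- changes$responder
  values <- cbind(changes, cohort[setdiff(names(cohort), "patient_id")])
  primary <- names(config$markers)[1]

  comparison <- note("comparison_table", .comparison_table(cohort, labels))
  marker_table <- note("marker_table",
                       .marker_table(values, labels, config$markers,
                                     config$level))

  cutoff <- note("cutoff", {
    if (config$cutoff_policy == "youden")
      youden_best_cutoff(values[[primary]], labels,
                         config$markers[[primary]])
    else structure(list(cutoff = config$fixed_cutoff, youden_j = NA_real_,
                        sens = NA_real_, spec = NA_real_,
                        direction = config$markers[[primary]]),
                   class = "cutoff_result")
  })
  metrics <- note("diagnostic_metrics", {
    if (is.null(cutoff)) stop("no cutoff available")
    t22 <- classify_at_cutoff(values[[primary]], labels, cutoff$cutoff,
                              config$markers[[primary]])
    diagnostic_summary(t22, config$level)
  })
  gray <- note("gray_zone",
               combined_zone(values[[primary]], labels,
                             n_boot = config$boot_n, level = config$level,
                             seed = config$boot_seed,
                             sn_floor = config$sn_floor,
                             sp_floor = config$sp_floor,
                             direction = config$markers[[primary]]))
  correlation <- note("correlation", {
    lrm <- linear_r2(changes$delta_pi_lrm, changes$delta_sv_lrm)
    all_iv <- four_quadrant_concordance(
      c(-changes$delta_pi_lrm, relative_increase(cohort$pi_t3, cohort$pi_t4)),
      c(-changes$delta_sv_lrm, changes$delta_sv_ve),
      exclusion = config$concordance_exclusion)
    list(r2_pi_sv_lrm = lrm, concordance = all_iv)
  })
  ss <- note("sample_size", {
    s <- config$samplesize
    n <- obuchowski_n(s$auc_alt, s$auc_null, s$ratio, s$alpha, s$power,
                      s$sided)
    n$n_planned <- inflate_for_dropout(n$n_total, s$dropout)
    n
  })

  structure(list(
    n = nrow(cohort), n_responders = sum(labels, na.rm = TRUE),
    n_label_missing = sum(is.na(labels)),
    changes = changes, comparison_table = comparison,
    marker_table = marker_table, primary_marker = primary,
    cutoff = cutoff, metrics = metrics, gray_zone = gray,
    correlation = correlation, sample_size = ss,
    config = config, stage_errors = errors
  ), class = "fluidroc_report")
}

#' @export
print.fluidroc_report <- function(x, ...) {
  cat(sprintf("Fluid-responsiveness evaluation: %d patients, %d responders (%.1f%%)\n",
              x$n, x$n_responders, 100 * x$n_responders / x$n))
  if (!is.null(x$marker_table)) {
    cat("\nMarkers (group mean ± SD; AUC with CI):\n")
    mt <- x$marker_table
    for (i in seq_len(nrow(mt)))
      cat(sprintf("  %-14s %6.2f ± %5.2f | %6.2f ± %5.2f | AUC %.2f (%.2f-%.2f)\n",
                  mt$marker[i], mt$resp_mean[i], mt$resp_sd[i],
                  mt$nonresp_mean[i], mt$nonresp_sd[i],
                  mt$auc[i], mt$auc_lo[i], mt$auc_hi[i]))
  }
  if (!is.null(x$cutoff)) { cat("\n"); print(x$cutoff) }
  if (!is.null(x$metrics)) { cat("\n"); print(x$metrics) }
  if (!is.null(x$gray_zone)) { cat("\n"); print(x$gray_zone) }
  if (!is.null(x$sample_size))
    cat(sprintf("\nPlanning echo: n_total = %d (+dropout -> %d)\n",
                x$sample_size$n_total, x$sample_size$n_planned))
  if (length(x$stage_errors)) {
    cat("\nStage errors:\n")
    for (nm in names(x$stage_errors))
      cat("  ", nm, ": ", x$stage_errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Write a machine-readable report
#'
#' Serializes the report bundle (tables, cutoff block, gray zone,
#' sample-size echo, stage errors) to JSON, and optionally the
#' human-readable text rendering alongside.
#'
#' @param report A `fluidroc_report`.
#' @param json_path Output JSON path.
#' @param txt_path Optional plain-text path (the `print` rendering).
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, txt_path = NULL) {
  stopifnot(inherits(report, "fluidroc_report"))
  payload <- list(
    n = report$n, n_responders = report$n_responders,
    primary_marker = report$primary_marker,
    marker_table = report$marker_table,
    comparison_table = report$comparison_table,
    cutoff = unclass(report$cutoff),
    metrics = if (!is.null(report$metrics)) list(
      sens = unclass(report$metrics$sens), spec = unclass(report$metrics$spec),
      ppv = unclass(report$metrics$ppv), npv = unclass(report$metrics$npv),
      lr_pos = unclass(report$metrics$lr_pos),
      lr_neg = unclass(report$metrics$lr_neg),
      counts = unclass(report$metrics$counts)),
    gray_zone = if (!is.null(report$gray_zone)) list(
      lower = report$gray_zone$lower, upper = report$gray_zone$upper,
      chosen = report$gray_zone$chosen,
      fractions = as.list(report$gray_zone$fractions)),
    correlation = report$correlation,
    sample_size = report$sample_size,
    stage_errors = report$stage_errors,
    seeds = list(bootstrap = report$config$boot_seed)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); on.exit({ sink(); close(con) })
    print(report)
  }
  invisible(json_path)
}
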