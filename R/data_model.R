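# Cohort table layout: one row per patient, columns "<variable>_<timepoint>".
# T1 = before LRM, T2 = after LRM, T3 = before VE, T4 = after VE.

.hemo_vars <- c("pi", "sv", "co", "sbp", "dbp", "map", "hr", "ppv", "svv", "pvi")
.hemo_tps  <- c("t1", "t2", "t3", "t4")
# variation indices may be 0; everything else must be strictly positive
.hemo_nonneg_vars <- c("ppv", "svv", "pvi")

.hemo_units <- c(
  pi = "%", sv = "mL", co = "L/min", sbp = "mmHg", dbp = "mmHg",
  map = "mmHg", hr = "beats/min", ppv = "%", svv = "%", pvi = "%"
)

#' Cohort CSV schema
#'
#' The canonical column layout for cohort tables: `patient_id` plus one
#' numeric column per variable and time point, named `<variable>_<timepoint>`
#' (e.g. `pi_t1`, `sv_t4`). T1/T2 bracket the lung recruitment maneuver,
#' T3/T4 the volume expansion. Files are comma-separated UTF-8 with `.` as
#' decimal separator; an empty cell means missing. Values are written with
#' up to 17 significant digits (`%.17g`) so that a write/read round trip is
#' bit exact.
#'
#' @return A data frame with one row per measurement column: `column`,
#'   `variable`, `timepoint`, `unit`, `constraint` (`"> 0"` or `">= 0"`).
#' @export
#' @examples
#' head(cohort_schema())
cohort_schema <- function() {
  grid <- expand.grid(variable = .hemo_vars, timepoint = .hemo_tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$variable, .hemo_vars)), ]
  data.frame(
    column     = paste(grid$variable, grid$timepoint, sep = "_"),
    variable   = grid$variable,
    timepoint  = toupper(grid$timepoint),
    unit       = unname(.hemo_units[grid$variable]),
    constraint = ifelse(grid$variable %in% .hemo_nonneg_vars, ">= 0", "> 0"),
    row.names  = NULL
  )
}

.measure_cols <- function() cohort_schema()$column

#' Read a cohort table from CSV
#'
#' Reads a per-patient table of hemodynamic measurements at the four time
#' points. The header must contain `patient_id` and all 40 measurement
#' columns of [cohort_schema()] (possibly under site-specific names remapped
#' through `col_map`). Empty cells become `NA`; values are validated against
#' the schema constraints.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector remapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(pi_t1 = "PI.baseline", patient_id = "id")`.
#' @param validate Validate values with [validate_cohort()] (default `TRUE`).
#' @return A data frame with `patient_id` (character) and the 40 numeric
#'   measurement columns in schema order.
#' @export
read_cohort <- function(path, col_map = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  wanted <- c("patient_id", .measure_cols())
  file_names <- wanted
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(!nzchar(names(col_map))))
      stop("col_map must be a named character vector (canonical = file name)")
    bad <- setdiff(names(col_map), wanted)
    if (length(bad))
      stop("col_map refers to unknown canonical column: ", bad[[1L]])
    idx <- match(names(col_map), wanted)
    file_names[idx] <- unname(col_map)
  }
  missing_cols <- file_names[!(file_names %in% names(raw))]
  if (length(missing_cols))
    stop("schema error: missing column '", missing_cols[[1L]], "'")
  raw <- raw[file_names]
  names(raw) <- wanted

  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (col in .measure_cols()) {
    cell <- trimws(raw[[col]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                   cell[bad[[1L]]], bad[[1L]], col))
    out[[col]] <- num
  }
  if (anyDuplicated(out$patient_id))
    stop("validation error: duplicate patient_id '",
         out$patient_id[duplicated(out$patient_id)][[1L]], "'")
  if (validate) validate_cohort(out)
  out
}

#' Validate a cohort table
#'
#' Checks schema invariants on a cohort data frame: all measurement columns
#' present and numeric, strictly positive values for pressures, flows, rates
#' and PI, non-negative variation indices, and `dbp <= map <= sbp` within a
#' 1 mmHg tolerance for rounded inputs.
#'
#' @param cohort A cohort data frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @return `cohort`, invisibly; stops with an informative error otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c("patient_id", .measure_cols()), names(cohort))
  if (length(missing_cols))
    stop("schema error: missing column '", missing_cols[[1L]], "'")
  if (anyDuplicated(cohort$patient_id))
    stop("validation error: duplicate patient_id")
  for (col in .measure_cols()) {
    v <- cohort[[col]]
    if (!is.numeric(v))
      stop("schema error: column '", col, "' is not numeric")
    var <- sub("_t[1-4]$", "", col)
    bad <- if (var %in% .hemo_nonneg_vars) which(!is.na(v) & v < 0)
           else which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf(
        "validation error: %s value %g for patient '%s' (column '%s')",
        if (var %in% .hemo_nonneg_vars) "negative" else "non-positive",
        v[bad[[1L]]], cohort$patient_id[bad[[1L]]], col))
  }
  for (tp in .hemo_tps) {
    sbp <- cohort[[paste0("sbp_", tp)]]
    dbp <- cohort[[paste0("dbp_", tp)]]
    map <- cohort[[paste0("map_", tp)]]
    ok <- is.na(sbp) | is.na(dbp) | is.na(map) |
      (dbp - 1 <= map & map <= sbp + 1)
    if (any(!ok))
      stop(sprintf(
        "validation error: pressure ordering dbp <= map <= sbp violated for patient '%s' at %s",
        cohort$patient_id[which(!ok)[[1L]]], toupper(tp)))
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: values are formatted with 17 significant
#' digits so that re-reading reproduces every present value bit-exactly;
#' missing values become empty cells.
#'
#' @param cohort A non-empty cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cannot write an empty cohort")
  out <- data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE)
  for (col in .measure_cols()) {
    v <- cohort[[col]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- ""
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
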