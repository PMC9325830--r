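# Data model and I/O for dermal absorption study tables.
#
# A study table holds per-dose-group *mean* results: one row per tested dose
# group of one product, with the applied dose in ug/cm^2 and the percentage of
# the applied dose recovered in each compartment (receptor fluid, skin,
# tape strips 1+2). Replicate-level (per-donor) data are out of scope.

.test_systems <- c("in_vitro_human", "in_vitro_rat", "in_vivo_rat")
.preparations <- c("concentrate", "dilution")
.endpoints <- c("RF", "POT")

#' CSV schema of a dermal absorption study table
#'
#' Column names (in order) expected by [read_study_table()] and written by
#' [write_study_table()]. Doses are in ug/cm2, concentrations in g a.i./L of
#' the test preparation, observation times in hours and all recoveries in
#' percent of the applied dose.
#'
#' @return Character vector of column names.
#' @export
study_table_columns <- function() {
  c("product_id", "active_id", "formulation_code", "test_system",
    "preparation", "applied_dose_ug_cm2", "concentration_g_L",
    "observation_time_h", "rf_pct", "skin_pct", "ts12_pct")
}

.required_columns <- c("product_id", "preparation", "applied_dose_ug_cm2")

#' Construct a validated study table
#'
#' @param records A data.frame with (a subset of) the columns named by
#'   [study_table_columns()]. `product_id`, `preparation`,
#'   `applied_dose_ug_cm2` and at least one recovery column (`rf_pct`,
#'   `skin_pct`) are required; missing optional columns are added as `NA`.
#' @param provenance Free-text source note attached to the table.
#'
#' @details Validation enforces: positive applied doses, non-negative
#'   recoveries, `ts12_pct <= skin_pct` where both are present, `preparation`
#'   in `{concentrate, dilution}`, `test_system` in
#'   `{in_vitro_human, in_vitro_rat, in_vivo_rat}` (where given), and no
#'   duplicate (product, preparation, test system, applied dose, observation
#'   time) keys. Zero recoveries are valid data at this layer; handling of
#'   zeros on the log scale is deferred to the modelling functions.
#'
#' @return A `study_table`: a data.frame with class `c("study_table",
#'   "data.frame")` and a `provenance` attribute.
#' @export
study_table <- function(records, provenance = "") {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_req <- setdiff(.required_columns, names(records))
  if (length(missing_req) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  if (!any(c("rf_pct", "skin_pct") %in% names(records))) {
    stop("schema error: need at least one recovery column (rf_pct, skin_pct)",
         call. = FALSE)
  }
  for (col in setdiff(study_table_columns(), names(records))) {
    records[[col]] <- if (col %in% c("product_id", "active_id",
                                     "formulation_code", "test_system",
                                     "preparation")) NA_character_ else NA_real_
  }
  records <- records[, study_table_columns()]
  .validate_records(records)
  structure(records,
            provenance = provenance,
            class = c("study_table", "data.frame"))
}

.validate_records <- function(rec) {
  bad <- function(idx, msg) {
    if (any(idx, na.rm = TRUE)) {
      stop("validation error in row(s) ", paste(which(idx), collapse = ", "),
           ": ", msg, call. = FALSE)
    }
  }
  if (!is.numeric(rec$applied_dose_ug_cm2)) {
    stop("parse error: applied_dose_ug_cm2 is not numeric", call. = FALSE)
  }
  bad(is.na(rec$applied_dose_ug_cm2), "applied dose missing or non-numeric")
  bad(rec$applied_dose_ug_cm2 <= 0, "applied dose must be > 0")
  for (col in c("rf_pct", "skin_pct", "ts12_pct")) {
    bad(rec[[col]] < 0, paste(col, "must be >= 0"))
  }
  bad(!is.na(rec$concentration_g_L) & rec$concentration_g_L <= 0,
      "concentration must be > 0 when present")
  bad(!is.na(rec$observation_time_h) & rec$observation_time_h <= 0,
      "observation time must be > 0 when present")
  both <- !is.na(rec$skin_pct) & !is.na(rec$ts12_pct)
  bad(both & rec$ts12_pct > rec$skin_pct,
      "ts12_pct exceeds skin_pct (tape strips 1+2 are part of the skin recovery)")
  bad(!is.na(rec$preparation) & !rec$preparation %in% .preparations,
      paste("preparation must be one of:", paste(.preparations, collapse = ", ")))
  bad(!is.na(rec$test_system) & !rec$test_system %in% .test_systems,
      paste("test_system must be one of:", paste(.test_systems, collapse = ", ")))
  key <- paste(rec$product_id, rec$preparation, rec$test_system,
               rec$applied_dose_ug_cm2, rec$observation_time_h, sep = "\r")
  bad(duplicated(key),
      "duplicate (product, preparation, test_system, applied dose, time) key")
  invisible(rec)
}

#' @export
print.study_table <- function(x, ...) {
  cat("Dermal absorption study table: ", nrow(x), " dose group(s), ",
      length(unique(x$product_id)), " product(s)\n", sep = "")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("Provenance:", prov, "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a study table from CSV
#'
#' Reads a comma-separated, dot-decimal, UTF-8 file with one header row using
#' the schema of [study_table_columns()], normalises Unicode minus signs to
#' ASCII, and validates the result. Rows violating an invariant abort the read
#' with a row-indexed diagnostic.
#'
#' @param path Path to the CSV file.
#' @param provenance Source note; defaults to the file path.
#' @return A [study_table()].
#' @export
read_study_table <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = TRUE)
  if (nrow(raw) == 0L) stop("schema error: empty table in ", path, call. = FALSE)
  num_cols <- c("applied_dose_ug_cm2", "concentration_g_L",
                "observation_time_h", "rf_pct", "skin_pct", "ts12_pct")
  for (col in intersect(num_cols, names(raw))) {
    v <- raw[[col]]
    if (is.character(v)) {
      v <- gsub("−", "-", trimws(v))  # U+2212 MINUS SIGN -> hyphen-minus
      v[v == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      failed <- which(!is.na(v) & is.na(vn))
      if (length(failed) > 0L) {
        stop("parse error: non-numeric value in column '", col, "', row(s) ",
             paste(failed, collapse = ", "), call. = FALSE)
      }
      v <- vn
    }
    raw[[col]] <- v
  }
  study_table(raw, provenance = provenance)
}

#' Write a study table to CSV
#'
#' @param table A [study_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert a relative absorption percentage to an absolute absorbed dose
#'
#' `absorbed = applied * da_rel_pct / 100`, both in ug/cm2.
#'
#' @param applied_dose Applied dose(s), ug/cm2; must be > 0.
#' @param da_rel_pct Relative dermal absorption, percent of applied dose;
#'   must be >= 0.
#' @return Absorbed dose(s), ug/cm2.
#' @export
#' @examples
#' relative_to_absolute(62.37, 5.2)  # 3.24 ug/cm2
relative_to_absolute <- function(applied_dose, da_rel_pct) {
  if (any(applied_dose <= 0)) stop("applied_dose must be > 0", call. = FALSE)
  if (any(da_rel_pct < 0)) stop("da_rel_pct must be >= 0", call. = FALSE)
  applied_dose * da_rel_pct / 100
}

#' Potentially absorbed dose as a percentage of the applied dose
#'
#' Receptor fluid plus skin (including stratum corneum) minus the first two
#' tape strips, which are conventionally treated as unabsorbed surface
#' material.
#'
#' @param rf_pct Receptor fluid recovery, percent.
#' @param skin_pct Skin recovery including stratum corneum, percent.
#' @param ts12_pct Recovery in tape strips 1+2, percent; must not exceed
#'   `skin_pct`.
#' @return Potentially absorbed dose, percent of applied dose.
#' @export
potentially_absorbed_pct <- function(rf_pct, skin_pct = 0, ts12_pct = 0) {
  if (any(rf_pct < 0) || any(skin_pct < 0) || any(ts12_pct < 0)) {
    stop("recoveries must be >= 0", call. = FALSE)
  }
  if (any(ts12_pct > skin_pct)) {
    stop("ts12_pct exceeds skin_pct: a negative skin contribution is impossible",
         call. = FALSE)
  }
  rf_pct + skin_pct - ts12_pct
}

#' Extract paired (applied dose, absorbed dose) series for an endpoint
#'
#' For endpoint `"RF"` the absorbed dose is the receptor fluid recovery (or
#' systemic recovery, for in vivo records) converted to ug/cm2; for `"POT"`
#' it is the potentially absorbed dose (RF + skin - tape strips 1+2). Records
#' lacking the compartments the endpoint needs are skipped with a warning.
#'
#' @param table A [study_table()].
#' @param endpoint `"RF"` or `"POT"`.
#' @param preparation Optional filter, `"concentrate"` or `"dilution"`.
#' @return A data.frame with columns `product_id`, `formulation_code`,
#'   `test_system`, `preparation`, `observation_time_h`, `concentration_g_L`,
#'   `applied`, `da_pct` and `absorbed` (ug/cm2).
#' @export
endpoint_series <- function(table, endpoint = c("RF", "POT"),
                            preparation = NULL) {
  stopifnot(inherits(table, "study_table"))
  endpoint <- match.arg(endpoint)
  rec <- as.data.frame(table)
  if (!is.null(preparation)) {
    preparation <- match.arg(preparation, .preparations)
    rec <- rec[!is.na(rec$preparation) & rec$preparation == preparation, ,
               drop = FALSE]
  }
  if (endpoint == "RF") {
    da <- rec$rf_pct
  } else {
    if (all(is.na(rec$skin_pct))) {
      stop("endpoint POT requested but no record carries skin data",
           call. = FALSE)
    }
    ts <- ifelse(is.na(rec$ts12_pct), 0, rec$ts12_pct)
    rf <- ifelse(is.na(rec$rf_pct), 0, rec$rf_pct)
    da <- ifelse(is.na(rec$skin_pct), NA_real_, rf + rec$skin_pct - ts)
  }
  keep <- !is.na(da)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) lack the compartments for endpoint ",
            endpoint, " and were skipped (rows ",
            paste(which(!keep), collapse = ", "), ")", call. = FALSE)
  }
  rec <- rec[keep, , drop = FALSE]
  da <- da[keep]
  if (nrow(rec) == 0L) {
    stop("no usable records for endpoint ", endpoint, call. = FALSE)
  }
  data.frame(
    product_id = rec$product_id,
    formulation_code = rec$formulation_code,
    test_system = rec$test_system,
    preparation = rec$preparation,
    observation_time_h = rec$observation_time_h,
    concentration_g_L = rec$concentration_g_L,
    applied = rec$applied_dose_ug_cm2,
    da_pct = da,
    absorbed = relative_to_absolute(rec$applied_dose_ug_cm2, da),
    stringsAsFactors = FALSE
  )
}
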