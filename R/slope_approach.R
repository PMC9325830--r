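# The "slope approach": reading a fitted log-log slope as evidence for or
# against competing regulatory hypotheses about dermal absorption.
#
# Slope 1 means absolute absorption is directly proportional to applied dose
# (a single relative absorption value holds at every dose); slope 0 means the
# absolute absorbed amount ignores the applied dose, which is the premise of
# the European pro-rata extrapolation; slopes between 0 and 1 mean relative
# absorption rises as dose falls, but less than pro-rata; negative slopes are
# biologically implausible (lower doses absorbing *more* in absolute terms).

.slope_categories <- c("ZERO", "BETWEEN_0_1", "ONE", "ABOVE_1", "UNCERTAIN")

#' Is a fitted slope compatible with a reference value?
#'
#' Compatibility means the two-sided `level` confidence interval of the slope
#' contains `value`; the interval is closed, so a boundary hit counts as
#' compatible.
#'
#' @param fit A [fit_loglog()] result with `n >= 3`.
#' @param value Reference slope (typically 1 or 0).
#' @param level Confidence level, default 0.95.
#' @return `TRUE` or `FALSE`.
#' @export
compatible_with <- function(fit, value, level = 0.95) {
  ci <- slope_ci(fit, level)
  value >= ci[1L] && value <= ci[2L]
}

#' Classify a slope confidence interval against multiple hypotheses
#'
#' Assigns exactly one category to an 80% confidence interval of a fitted
#' slope, so that four hypotheses (slope 0, between 0 and 1, 1, above 1) are
#' each assessed with 95% confidence. Rules apply in order:
#' \enumerate{
#'   \item interval entirely below 0: `UNCERTAIN` (a negative slope is
#'     biologically implausible, typically an artefact of stratum corneum
#'     residue);
#'   \item contains both 0 and 1: `UNCERTAIN` (too wide to conclude);
#'   \item contains 1 only: `ONE`;
#'   \item contains 0 only: `ZERO`;
#'   \item entirely above 1: `ABOVE_1`;
#'   \item entirely inside (0, 1): `BETWEEN_0_1`.
#' }
#' Intervals are closed; boundary containment counts as containing. When the
#' whole interval sits just above 1 (`lo` in (1, 1.1]) the classification
#' carries a proximity note, since such slopes are often indistinguishable
#' from 1 in practice.
#'
#' @param ci Numeric `c(lo, hi)` with `lo <= hi`, e.g. from
#'   `slope_ci(fit, 0.80)`.
#' @param ci_level The level the interval was computed at (metadata).
#' @param stratum Text label.
#' @return An object of class `slope_classification` with elements
#'   `category`, `ci`, `ci_level`, `stratum`, `note`.
#' @export
classify_slope <- function(ci, ci_level = 0.80, stratum = "") {
  lo <- unname(ci[1L]); hi <- unname(ci[2L])
  if (is.na(lo) || is.na(hi) || lo > hi) {
    stop("malformed interval: need lo <= hi", call. = FALSE)
  }
  category <-
    if (hi < 0) "UNCERTAIN"
    else if (lo <= 0 && hi >= 1) "UNCERTAIN"
    else if (lo <= 1 && hi >= 1) "ONE"
    else if (lo <= 0 && hi >= 0) "ZERO"
    else if (lo > 1) "ABOVE_1"
    else "BETWEEN_0_1"
  note <- if (category == "ABOVE_1" && lo <= 1.1) {
    "slope greater than but very close to 1"
  } else {
    ""
  }
  structure(list(category = category, ci = c(lo = lo, hi = hi),
                 ci_level = ci_level, stratum = stratum, note = note),
            class = "slope_classification")
}

#' @export
print.slope_classification <- function(x, ...) {
  cat(sprintf("Slope classification: %s  [%.3f, %.3f] at %.0f%% CI%s%s\n",
              x$category, x$ci[1L], x$ci[2L], 100 * x$ci_level,
              if (nzchar(x$stratum)) paste0("  (", x$stratum, ")") else "",
              if (nzchar(x$note)) paste0("  - ", x$note) else ""))
  invisible(x)
}

.interpretations <- list(
  ABOVE_1 = list(
    absolute_penetration = "Decreases with decreasing doses (overly dose-proportional)",
    relative_penetration = "Decreases with decreasing dose (more than dose-proportional)",
    small_dose_limit = "Intersects the abscissa, i.e. 0% absorption: very small doses are not absorbed",
    adme = "ADME processes reduce exposure/toxicity at lower applied doses",
    internal_exposure = "Smaller doses result in less systemic exposure than higher doses",
    plausibility = "Plausible"),
  ONE = list(
    absolute_penetration = "Decreases with decreasing doses (directly dose-proportional)",
    relative_penetration = "Constant and independent of applied dose",
    small_dose_limit = "Constant",
    adme = "ADME processes do not affect exposure/toxicity",
    internal_exposure = "Smaller doses result in less systemic exposure than higher doses",
    plausibility = "Plausible"),
  BETWEEN_0_1 = list(
    absolute_penetration = "Decreases with decreasing doses (less than dose-proportional)",
    relative_penetration = "Increases with decreasing dose (less than dose-proportional)",
    small_dose_limit = "Intersects the identity line, i.e. 100% absorption: very small doses are completely absorbed",
    adme = "ADME processes increase exposure/toxicity at lower applied doses",
    internal_exposure = "Smaller doses result in less systemic exposure than higher doses",
    plausibility = "Plausible"),
  ZERO = list(
    absolute_penetration = "Constant and independent of dose (EFSA pro-rata approach)",
    relative_penetration = "Increases with decreasing dose (inverse correlation)",
    small_dose_limit = "Constant absolute absorbed amount; relative absorption grows toward 100% as dose decreases (unbounded pro-rata extrapolation)",
    adme = "ADME processes increase exposure/toxicity at lower applied doses",
    internal_exposure = "All applied doses result in the same systemic exposure",
    plausibility = "Implausible"),
  UNCERTAIN = list(
    absolute_penetration = "Inconclusive, or increases with decreasing doses (inverse correlation) for a negative slope",
    relative_penetration = "Inconclusive",
    small_dose_limit = "Inconclusive",
    adme = "Inconclusive",
    internal_exposure = "Lower applied doses may result in higher systemic exposure (negative slope)",
    plausibility = "Implausible (negative slope) or no conclusion (wide interval)")
)

#' Regulatory interpretation of a slope regime
#'
#' Returns the interpretation ledger for a slope category: what the regime
#' implies for absolute and relative penetration, the small-dose
#' extrapolation limit in deterministic exposure calculation, the ADME
#' reading (were the assay modelling in vivo absorption), the predicted
#' internal exposure, and a biological plausibility verdict.
#'
#' @param category One of `"ZERO"`, `"BETWEEN_0_1"`, `"ONE"`, `"ABOVE_1"`,
#'   `"UNCERTAIN"`, or a `slope_classification`.
#' @return A named list of interpretation texts (class
#'   `slope_interpretation`).
#' @export
interpret_slope <- function(category) {
  if (inherits(category, "slope_classification")) category <- category$category
  category <- match.arg(category, .slope_categories)
  structure(c(list(category = category), .interpretations[[category]]),
            class = "slope_interpretation")
}

#' @export
print.slope_interpretation <- function(x, ...) {
  cat("Interpretation of slope regime ", x$category, ":\n", sep = "")
  for (f in setdiff(names(x), "category")) {
    cat("  ", format(f, width = 22), x[[f]], "\n")
  }
  invisible(x)
}

#' Summarise slope classifications
#'
#' Counts and integer-rounded percentages per category over a collection of
#' classifications, in the fixed category order ZERO, BETWEEN_0_1, ONE,
#' ABOVE_1, UNCERTAIN.
#'
#' @param classifications A list of `slope_classification` objects (or a
#'   character vector of categories).
#' @return A data.frame with columns `category`, `n`, `pct` (rounded to
#'   integer percent of the total).
#' @export
classification_summary <- function(classifications) {
  if (is.list(classifications)) {
    cats <- vapply(classifications, function(cl) {
      if (inherits(cl, "slope_classification")) cl$category else as.character(cl)
    }, character(1L))
  } else {
    cats <- as.character(classifications)
  }
  if (length(cats) == 0L) stop("need >= 1 classification", call. = FALSE)
  stopifnot(all(cats %in% .slope_categories))
  n <- table(factor(cats, levels = .slope_categories))
  data.frame(category = .slope_categories,
             n = as.integer(n),
             pct = as.integer(round(100 * as.integer(n) / length(cats))),
             stringsAsFactors = FALSE)
}

#' Classification table for export
#'
#' @param fits A `loglog_fit_list` (or single fit).
#' @param level CI level used for classification (default 0.80).
#' @return A data.frame: stratum, slope, ci_lo, ci_hi, category, note.
#' @export
classify_fits <- function(fits, level = 0.80) {
  if (inherits(fits, "loglog_fit")) fits <- structure(list(fits))
  rows <- lapply(fits, function(f) {
    if (f$n < 3L) {
      return(data.frame(stratum = f$stratum, slope = f$slope,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        category = "UNCERTAIN",
                        note = "no CI computable (n < 3)",
                        stringsAsFactors = FALSE))
    }
    ci <- slope_ci(f, level)
    cl <- classify_slope(ci, ci_level = level, stratum = f$stratum)
    data.frame(stratum = f$stratum, slope = f$slope,
               ci_lo = unname(ci[1L]), ci_hi = unname(ci[2L]),
               category = cl$category, note = cl$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
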