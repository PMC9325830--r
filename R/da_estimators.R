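# Average dermal absorption estimators.
#
# Under an assumed slope of 1 the log-log model intercept reduces to the mean
# of log10(absorbed) - log10(applied); its back-transformation
# DA_ave = 10^intercept * 100 is a single relative absorption value valid
# across exposure doses, and is algebraically the geometric mean of the
# per-dose-group relative absorption percentages. A free-slope fit yields the
# model-based analogue DA_rel|model = 10^(fitted intercept) * 100.

#' Slope-1 intercept of the log-log dose-absorption model
#'
#' With the slope fixed at 1 the least-squares intercept is the mean of the
#' per-group differences `log10(absorbed) - log10(applied)`.
#'
#' @param applied Applied doses, ug/cm2; all > 0.
#' @param absorbed Absorbed doses, ug/cm2; all > 0.
#' @return The intercept in log10 units.
#' @export
#' @examples
#' intercept_slope1(c(62.37, 31.43, 22.71, 16.45),
#'                  c(3.24, 2.81, 2.85, 2.30))  # about -1.02
intercept_slope1 <- function(applied, absorbed) {
  stopifnot(length(applied) == length(absorbed), length(applied) >= 1L)
  bad <- which(is.na(applied) | is.na(absorbed) | applied <= 0 | absorbed <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or missing dose in pair(s) ",
         paste(bad, collapse = ", "),
         ": both applied and absorbed must be > 0", call. = FALSE)
  }
  mean(log10(absorbed) - log10(applied))
}

.new_da_estimate <- function(intercept, method, endpoint, n_groups, stratum) {
  structure(list(value_pct = 10^intercept * 100,
                 intercept = intercept,
                 method = method,
                 endpoint = endpoint,
                 n_groups = n_groups,
                 stratum = stratum),
            class = "da_estimate")
}

#' @export
print.da_estimate <- function(x, ...) {
  cat(sprintf(
    "DA estimate: %.2f%% (%s, endpoint %s, %d group(s)%s)\n  intercept %.4f log10 units\n",
    x$value_pct, x$method, x$endpoint, x$n_groups,
    if (nzchar(x$stratum)) paste0(", ", x$stratum) else "", x$intercept))
  invisible(x)
}

#' Average dermal absorption value assuming a slope of 1
#'
#' `DA_ave [%] = 10^mean(log10(absorbed) - log10(applied)) * 100`: the
#' back-transformed slope-1 intercept, equal to the geometric mean of the
#' per-group relative absorption percentages. When at least three groups are
#' available a free-slope companion fit is run, and a non-fatal warning is
#' emitted if its slope exceeds 1: there a single slope-1 average may
#' under-predict absorption at high doses and such products warrant
#' case-by-case assessment.
#'
#' @inheritParams intercept_slope1
#' @param endpoint `"RF"` or `"POT"` (provenance metadata).
#' @param stratum Text label.
#' @param check_slope Run the companion free-slope fit and warn when its
#'   point estimate exceeds 1 (default `TRUE`).
#' @return A `da_estimate` with `method = "slope1_average"`.
#' @export
#' @examples
#' da_ave(c(62.37, 31.43, 22.71, 16.45), c(3.24, 2.81, 2.85, 2.30))  # 9.50%
da_ave <- function(applied, absorbed, endpoint = c("RF", "POT"),
                   stratum = "", check_slope = TRUE) {
  endpoint <- match.arg(endpoint)
  ic <- intercept_slope1(applied, absorbed)
  if (check_slope && length(applied) >= 3L &&
      stats::sd(log10(applied)) > 0) {
    companion <- fit_loglog(applied, absorbed, endpoint = endpoint,
                            stratum = stratum)
    if (companion$slope > 1) {
      warning(sprintf(
        "fitted slope %.3f exceeds 1: a slope-1 average may under-predict ",
        companion$slope),
        "absorption at higher doses; assess case-by-case", call. = FALSE)
    }
  }
  .new_da_estimate(ic, "slope1_average", endpoint, length(applied), stratum)
}

#' Average dermal absorption for one stratum of a study table
#'
#' Convenience wrapper extracting the endpoint series from a study table and
#' computing [da_ave()]. Concentrates and in-use dilutions have very
#' different physico-chemical properties and must never be pooled into one
#' average, so a `preparation` filter is required whenever the table
#' contains both.
#'
#' @param table A [study_table()].
#' @param endpoint `"RF"` or `"POT"`.
#' @param preparation `"concentrate"` or `"dilution"`; may be omitted only
#'   when the table holds a single preparation.
#' @param product Optional product filter.
#' @param ... Passed to [da_ave()].
#' @return A `da_estimate`.
#' @export
da_ave_table <- function(table, endpoint = c("RF", "POT"),
                         preparation = NULL, product = NULL, ...) {
  endpoint <- match.arg(endpoint)
  preps <- unique(stats::na.omit(table$preparation))
  if (is.null(preparation)) {
    if (length(preps) > 1L) {
      stop("table mixes concentrates and dilutions: these must not be ",
           "pooled into one average; pass preparation = \"concentrate\" or ",
           "\"dilution\"", call. = FALSE)
    }
    preparation <- if (length(preps) == 1L) preps else NULL
  }
  ser <- endpoint_series(table, endpoint, preparation = preparation)
  if (!is.null(product)) {
    ser <- ser[ser$product_id %in% product, , drop = FALSE]
    if (nrow(ser) == 0L) stop("no records for product ", product, call. = FALSE)
  }
  stratum <- paste(c(product, preparation), collapse = "/")
  da_ave(ser$applied, ser$absorbed, endpoint = endpoint, stratum = stratum, ...)
}

#' Model-based relative dermal absorption value
#'
#' `DA_rel|model [%] = 10^intercept * 100` from a free-slope fit of
#' log10(absorbed dose) on log10(applied dose). Only meaningful for the
#' `absolute_vs_dose` model form, whose intercept is the log10 absorbed dose
#' at an applied dose of 1 ug/cm2.
#'
#' @param fit A [fit_loglog()] result with
#'   `model_form = "absolute_vs_dose"`, or a bare numeric intercept in log10
#'   units (as read off a report table).
#' @param endpoint,stratum Metadata (taken from the fit when one is given).
#' @return A `da_estimate` with `method = "fitted_model"`.
#' @export
#' @examples
#' da_rel_model(-1.57)$value_pct  # 2.69%
da_rel_model <- function(fit, endpoint = "RF", stratum = "") {
  if (inherits(fit, "loglog_fit")) {
    if (fit$model_form != "absolute_vs_dose") {
      stop("da_rel_model() needs a fit of model_form 'absolute_vs_dose'; ",
           "the intercept of a concentration-form fit is not an absorption ",
           "value", call. = FALSE)
    }
    return(.new_da_estimate(fit$intercept, "fitted_model", fit$endpoint,
                            fit$n, fit$stratum))
  }
  stopifnot(is.numeric(fit), length(fit) == 1L)
  .new_da_estimate(fit, "fitted_model", endpoint, 1L, stratum)
}

#' Predict the internal (absorbed) dose from a DA estimate
#'
#' `absorbed = applied * value_pct / 100`.
#'
#' @param applied Applied dose(s), ug/cm2; > 0.
#' @param da A `da_estimate` (or a bare percentage).
#' @return Predicted absorbed dose(s), ug/cm2.
#' @export
predict_internal_dose <- function(applied, da) {
  if (any(applied <= 0)) stop("applied dose must be > 0", call. = FALSE)
  pct <- if (inherits(da, "da_estimate")) da$value_pct else da
  applied * pct / 100
}

#' Worked per-group DA_ave calculation table
#'
#' Reproduces, for one product, the full hand calculation: per dose group
#' the applied dose, relative absorption, absolute absorbed dose, the log10
#' values and their difference; then the mean difference (the slope-1
#' intercept), DA_ave, the per-group absorbed dose predicted from DA_ave,
#' and column sums of applied, observed absorbed and predicted absorbed.
#' All arithmetic is carried at full floating precision; rounding to two
#' decimals happens only in the print/render methods.
#'
#' @param table A [study_table()].
#' @param endpoint `"RF"` or `"POT"`.
#' @param product Product to tabulate; may be omitted for a single-product
#'   table. With multiple products and no filter, a named list of worked
#'   tables (one per product) is returned.
#' @param preparation Optional preparation filter (required if mixed).
#' @return An object of class `da_worked_table`: `groups` (data.frame with
#'   columns `applied`, `da_pct`, `absorbed`, `log10_applied`,
#'   `log10_absorbed`, `log_diff`, `predicted`), `mean_diff`, `da_ave` (a
#'   `da_estimate`), `slope` (free-slope companion fit, `NA` if n < 2),
#'   `sums` (applied, absorbed, predicted), `product`, `endpoint`.
#' @export
worked_table <- function(table, endpoint = c("RF", "POT"), product = NULL,
                         preparation = NULL) {
  endpoint <- match.arg(endpoint)
  products <- unique(table$product_id)
  if (is.null(product) && length(products) > 1L) {
    out <- lapply(products, function(p) {
      worked_table(table, endpoint, product = p, preparation = preparation)
    })
    names(out) <- products
    return(out)
  }
  if (is.null(product)) product <- products
  ser <- endpoint_series(table, endpoint, preparation = preparation)
  ser <- ser[ser$product_id == product, , drop = FALSE]
  if (nrow(ser) == 0L) stop("no usable groups for product ", product,
                            call. = FALSE)
  applied <- ser$applied
  absorbed <- ser$absorbed
  md <- intercept_slope1(applied, absorbed)
  est <- suppressWarnings(
    da_ave(applied, absorbed, endpoint = endpoint, stratum = product)
  )
  slope <- if (length(applied) >= 2L && stats::sd(log10(applied)) > 0) {
    fit_loglog(applied, absorbed, endpoint = endpoint, stratum = product)$slope
  } else {
    NA_real_
  }
  predicted <- predict_internal_dose(applied, est)
  groups <- data.frame(
    applied = applied, da_pct = ser$da_pct, absorbed = absorbed,
    log10_applied = log10(applied), log10_absorbed = log10(absorbed),
    log_diff = log10(absorbed) - log10(applied), predicted = predicted
  )
  structure(list(groups = groups, mean_diff = md, da_ave = est, slope = slope,
                 sums = c(applied = sum(applied), absorbed = sum(absorbed),
                          predicted = sum(predicted)),
                 product = product, endpoint = endpoint),
            class = "da_worked_table")
}

#' @export
print.da_worked_table <- function(x, ...) {
  cat("DA_ave worked calculation - product ", x$product, ", endpoint ",
      x$endpoint, "\n", sep = "")
  if (!is.na(x$slope)) cat(sprintf("Free-slope fit: slope %.3f\n", x$slope))
  g <- x$groups
  disp <- data.frame(
    `applied (ug/cm2)` = sprintf("%.2f", g$applied),
    `DA (%)` = sprintf("%.2f", g$da_pct),
    `absorbed (ug/cm2)` = sprintf("%.2f", g$absorbed),
    `log10 applied` = sprintf("%.2f", g$log10_applied),
    `log10 absorbed` = sprintf("%.2f", g$log10_absorbed),
    `difference` = sprintf("%.2f", g$log_diff),
    `predicted via DA_ave` = sprintf("%.2f", g$predicted),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  cat(sprintf("Sum: applied %.2f, absorbed %.2f, predicted %.2f\n",
              x$sums["applied"], x$sums["absorbed"], x$sums["predicted"]))
  cat(sprintf("Mean difference %.2f  =>  DA_ave %.2f%%\n",
              x$mean_diff, x$da_ave$value_pct))
  invisible(x)
}

#' Render a worked table to CSV or Markdown
#'
#' Columns follow the hand-calculation order (applied dose, DA%, absorbed,
#' log10 applied, log10 absorbed, difference, predicted absorbed), values
#' rounded to two decimals, with a trailing Sum row.
#'
#' @param x A [worked_table()] result.
#' @param path Output path for `format = "csv"`; ignored for markdown.
#' @param format `"csv"` or `"markdown"`.
#' @return For `"csv"`, `path` invisibly; for `"markdown"`, a character
#'   vector of lines.
#' @export
render_worked_table <- function(x, path = NULL, format = c("csv", "markdown")) {
  stopifnot(inherits(x, "da_worked_table"))
  format <- match.arg(format)
  g <- x$groups
  body <- data.frame(
    applied_dose_ug_cm2 = round(g$applied, 2),
    da_pct = round(g$da_pct, 2),
    absorbed_dose_ug_cm2 = round(g$absorbed, 2),
    log10_applied = round(g$log10_applied, 2),
    log10_absorbed = round(g$log10_absorbed, 2),
    difference = round(g$log_diff, 2),
    absorbed_using_da_ave = round(g$predicted, 2))
  sums <- data.frame(applied_dose_ug_cm2 = round(x$sums[["applied"]], 2),
                     da_pct = NA, absorbed_dose_ug_cm2 = round(x$sums[["absorbed"]], 2),
                     log10_applied = NA, log10_absorbed = NA, difference = NA,
                     absorbed_using_da_ave = round(x$sums[["predicted"]], 2))
  out <- rbind(body, sums)
  out <- cbind(row = c(rep(x$product, nrow(body)), "Sum"), out)
  if (format == "csv") {
    stopifnot(!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  header <- paste0("| ", paste(names(out), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
  rows <- apply(out, 1L, function(r) {
    paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
  })
  c(header, sep, rows)
}

#' Pro-rata extrapolation of a relative absorption value
#'
#' The concentration-based European convention: when the target in-use
#' concentration lies below the tested range, the tested relative absorption
#' value is scaled up inversely with concentration,
#' `da_target = da_tested * conc_tested / conc_target`, capped at 100%
#' (the uncapped rule is unbounded, and a relative absorption above 100% is
#' physically meaningless). Intended for downward extrapolation; a warning
#' is given when `conc_target > conc_tested`.
#'
#' @param da_tested_pct Tested relative absorption, percent; > 0.
#' @param conc_tested Tested concentration, g/L; > 0.
#' @param conc_target Target concentration, g/L; > 0.
#' @return Extrapolated relative absorption, percent (capped at 100).
#' @export
#' @examples
#' pro_rata(1, 1.0, 0.1)  # 10%
pro_rata <- function(da_tested_pct, conc_tested, conc_target) {
  if (any(c(da_tested_pct, conc_tested, conc_target) <= 0)) {
    stop("pro_rata() needs strictly positive inputs", call. = FALSE)
  }
  if (conc_target > conc_tested) {
    warning("conc_target exceeds conc_tested: pro-rata is meant for ",
            "extrapolation below the tested range", call. = FALSE)
  }
  pmin(100, da_tested_pct * conc_tested / conc_target)
}
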