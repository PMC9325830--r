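# Log-log linear models of dermal absorption.
#
# Two competing model forms:
#   absolute_vs_dose:          log10(absorbed dose)  ~ log10(applied dose)
#   relative_vs_concentration: log10(relative DA %)  ~ log10(concentration)
# The first treats the applied dose as the driver of absorption (slope 1 =
# direct dose proportionality); the second is the concentration-centred view
# underlying the European pro-rata convention (slope 0 = relative absorption
# independent of dose; slope -1 = exact pro-rata).

.model_forms <- c("absolute_vs_dose", "relative_vs_concentration")

#' Fit a log10-log10 linear model
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`. Pairs with a
#' non-positive value on either axis cannot be represented on the log scale
#' and are excluded with a warning (dose-group *means* are strictly positive
#' in practice, so exclusions normally signal data problems). Optionally a
#' positive floor can be substituted for non-positive responses, mimicking a
#' limit-of-quantification imputation; it is off by default because silent
#' substitution biases slopes.
#'
#' @param x Positive predictor values: applied dose (ug/cm2) for
#'   `absolute_vs_dose`, concentration (g/L) for `relative_vs_concentration`.
#' @param y Positive response values: absorbed dose (ug/cm2) or relative
#'   absorption (percent), matching `model_form`.
#' @param model_form `"absolute_vs_dose"` or `"relative_vs_concentration"`.
#' @param endpoint `"RF"` or `"POT"` (metadata carried into the fit).
#' @param stratum Text label for the data subset fitted.
#' @param floor Optional positive value substituted for `y <= 0` instead of
#'   exclusion.
#' @return An object of class `loglog_fit`: slope, intercept (log10 units),
#'   their standard errors, `r2`, `aic` (Gaussian ML convention, see
#'   [model_aic()]), `n`, `residual_sd`, `rss`, plus the metadata.
#' @export
#' @examples
#' fit <- fit_loglog(c(62.37, 31.43, 22.71, 16.45),
#'                   c(3.24, 2.81, 2.85, 2.30))
#' round(fit$slope, 3)
fit_loglog <- function(x, y, model_form = c("absolute_vs_dose",
                                            "relative_vs_concentration"),
                       endpoint = c("RF", "POT"), stratum = "all",
                       floor = NULL) {
  model_form <- match.arg(model_form)
  endpoint <- match.arg(endpoint)
  stopifnot(length(x) == length(y))
  if (!is.null(floor)) {
    stopifnot(floor > 0)
    y[y <= 0] <- floor
  }
  usable <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  if (any(!usable)) {
    warning(sum(!usable), " pair(s) with non-positive or missing values ",
            "excluded from the log-scale fit", call. = FALSE)
  }
  x <- x[usable]; y <- y[usable]
  n <- length(x)
  if (n < 2L) {
    stop("insufficient data: need >= 2 usable (x > 0, y > 0) pairs, got ", n,
         call. = FALSE)
  }
  lx <- log10(x); ly <- log10(y)
  if (stats::sd(lx) == 0) {
    stop("singular design: all predictor values identical", call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # perfect fits trip summary.lm
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ly - mean(ly))^2)
  out <- list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    se_slope = unname(sm$coefficients[2L, 2L]),
    se_intercept = unname(sm$coefficients[1L, 2L]),
    r2 = if (tss > 0) 1 - rss / tss else 1,
    n = n,
    rss = rss,
    residual_sd = if (n > 2L) sqrt(rss / (n - 2L)) else 0,
    model_form = model_form,
    endpoint = endpoint,
    stratum = stratum,
    log10_x = lx,
    log10_y = ly
  )
  out$aic <- .gaussian_aic(rss, n)
  class(out) <- "loglog_fit"
  out
}

# Full Gaussian maximum-likelihood AIC with k = 3 estimated parameters
# (slope, intercept, residual variance): AIC = n*log(2*pi*RSS/n) + n + 2k.
# Matches stats::AIC() on an lm object. RSS = 0 (numerically, below 1e-12)
# returns -Inf as a sentinel.
.gaussian_aic <- function(rss, n, k = 3) {
  if (rss <= 1e-12) return(-Inf)
  n * log(2 * pi * rss / n) + n + 2 * k
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("Log-log linear fit [", x$model_form, ", endpoint ", x$endpoint,
      ", stratum '", x$stratum, "']\n", sep = "")
  cat(sprintf("  slope %.4f (SE %.4f), intercept %.4f (SE %.4f)\n",
              x$slope, x$se_slope, x$intercept, x$se_intercept))
  cat(sprintf("  n = %d, R2 = %.3f, AIC = %.2f, residual SD = %.4f\n",
              x$n, x$r2, x$aic, x$residual_sd))
  invisible(x)
}

#' Confidence interval for a fitted slope
#'
#' Two-sided Wald t-interval, `slope +/- t(1 - (1-level)/2, df = n - 2) *
#' se_slope`.
#'
#' @param fit A [fit_loglog()] result.
#' @param level Confidence level in (0, 1); 0.95 for the single-hypothesis
#'   check against slope 1, 0.80 for the multi-hypothesis classification
#'   scheme (four hypotheses, each assessed with 95% confidence).
#' @return Numeric vector `c(lo, hi)`.
#' @export
slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "loglog_fit"), level > 0, level < 1)
  if (fit$n < 3L) {
    stop("degrees-of-freedom error: slope CI needs n >= 3 (df = n - 2 >= 1)",
         call. = FALSE)
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2L)
  c(lo = fit$slope - tq * fit$se_slope,
    hi = fit$slope + tq * fit$se_slope)
}

#' Akaike information criterion of a log-log fit
#'
#' Full Gaussian maximum-likelihood convention including the `2*pi` term,
#' with `k = 3` parameters (slope, intercept, residual variance):
#' `AIC = n*log(2*pi*RSS/n) + n + 2k`. A perfect fit (`RSS = 0`) returns
#' `-Inf` as a documented sentinel rather than an error.
#'
#' @param fit A [fit_loglog()] result.
#' @return The AIC (numeric scalar; `-Inf` if `RSS = 0`).
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "loglog_fit"))
  .gaussian_aic(fit$rss, fit$n)
}

#' Fit a mixed-effects log-log model with product random intercepts
#'
#' Random-intercept-by-product linear mixed model on the log10 scale,
#' for databases where several products each contribute multiple dose
#' groups. Variance components are estimated by REML; the reported AIC comes
#' from the ML refit so that models with different fixed effects remain
#' comparable. Marginal and conditional R-squared follow the variance
#' decomposition for mixed models: with `s2_f` the variance of the
#' fixed-effect predictions, `s2_u` the random-intercept variance and `s2_e`
#' the residual variance,
#' `R2_marginal = s2_f / (s2_f + s2_u + s2_e)` and
#' `R2_conditional = (s2_f + s2_u) / (s2_f + s2_u + s2_e)`.
#'
#' @param table A [study_table()].
#' @param model_form,endpoint As in [fit_loglog()].
#' @param preparation Optional preparation filter.
#' @return An object of class `mixed_fit` with elements `slope`, `intercept`,
#'   `var_fixed`, `var_random`, `var_resid`, `r2_marginal`, `r2_conditional`,
#'   `aic`, `n_products`, `n_obs`.
#' @export
fit_mixed <- function(table, model_form = c("absolute_vs_dose",
                                            "relative_vs_concentration"),
                      endpoint = c("RF", "POT"), preparation = NULL) {
  model_form <- match.arg(model_form)
  endpoint <- match.arg(endpoint)
  ser <- endpoint_series(table, endpoint, preparation = preparation)
  d <- .model_frame(ser, model_form)
  tab <- table(d$product)
  if (length(tab) < 2L || sum(tab >= 2L) < 2L) {
    stop("degenerate grouping: need >= 2 products with >= 2 usable records ",
         "each; use fit_loglog() for a single product", call. = FALSE)
  }
  reml <- lme4::lmer(ly ~ lx + (1 | product), data = d, REML = TRUE)
  ml <- lme4::refitML(reml)
  vc <- lme4::VarCorr(reml)
  var_random <- as.numeric(vc$product[1L, 1L])
  var_resid <- attr(vc, "sc")^2
  fe <- lme4::fixef(reml)
  var_fixed <- stats::var(as.numeric(fe[1L] + fe[2L] * d$lx))
  tot <- var_fixed + var_random + var_resid
  out <- list(
    slope = unname(fe[2L]),
    intercept = unname(fe[1L]),
    var_fixed = var_fixed,
    var_random = var_random,
    var_resid = var_resid,
    r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_random) / tot,
    aic = stats::AIC(ml),
    n_products = length(tab),
    n_obs = nrow(d),
    model_form = model_form,
    endpoint = endpoint
  )
  class(out) <- "mixed_fit"
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Mixed-effects log-log fit [", x$model_form, ", endpoint ", x$endpoint,
      "], random intercept by product\n", sep = "")
  cat(sprintf("  slope %.4f, intercept %.4f (%d products, %d obs)\n",
              x$slope, x$intercept, x$n_products, x$n_obs))
  cat(sprintf("  variances: fixed %.4f, product %.4f, residual %.4f\n",
              x$var_fixed, x$var_random, x$var_resid))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f; AIC (ML) %.2f\n",
              x$r2_marginal, x$r2_conditional, x$aic))
  invisible(x)
}

# Build the log10 modelling frame for a model form, dropping rows that are
# unusable on the log scale (with a warning, as in fit_loglog).
.model_frame <- function(ser, model_form) {
  if (model_form == "absolute_vs_dose") {
    x <- ser$applied; y <- ser$absorbed
  } else {
    x <- ser$concentration_g_L; y <- ser$da_pct
  }
  usable <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  if (any(!usable)) {
    warning(sum(!usable), " record(s) unusable on the log scale for ",
            model_form, " and excluded", call. = FALSE)
  }
  if (sum(usable) < 2L) {
    stop("insufficient data for ", model_form, ": ", sum(usable),
         " usable record(s)", call. = FALSE)
  }
  data.frame(lx = log10(x[usable]), ly = log10(y[usable]),
             product = factor(ser$product_id[usable]))
}

#' Compare the dose-driven and concentration-driven model forms
#'
#' Fits `absolute_vs_dose` and `relative_vs_concentration` on the same
#' records and reports slope, R2 and AIC side by side. Note the two model
#' forms have *different responses* (log10 absolute absorbed vs log10
#' relative absorption); their AICs are compared naively, without a Jacobian
#' adjustment for the change of response variable, and the returned object
#' carries `different_response = TRUE` to flag this.
#'
#' @param table A [study_table()].
#' @param endpoint `"RF"` or `"POT"`.
#' @param preparation Optional preparation filter.
#' @return A data.frame with one row per model form (columns `model_form`,
#'   `slope`, `r2`, `aic`, `n`) and attribute `different_response`. If the
#'   concentration column is entirely missing, only the dose-form row is
#'   returned, with a warning.
#' @export
compare_model_forms <- function(table, endpoint = c("RF", "POT"),
                                preparation = NULL) {
  endpoint <- match.arg(endpoint)
  ser <- endpoint_series(table, endpoint, preparation = preparation)
  dose_fit <- fit_loglog(ser$applied, ser$absorbed,
                         model_form = "absolute_vs_dose",
                         endpoint = endpoint)
  rows <- data.frame(model_form = "absolute_vs_dose",
                     slope = dose_fit$slope, r2 = dose_fit$r2,
                     aic = dose_fit$aic, n = dose_fit$n,
                     stringsAsFactors = FALSE)
  if (all(is.na(ser$concentration_g_L))) {
    warning("concentration column empty: returning dose-form fit only",
            call. = FALSE)
  } else {
    conc_fit <- fit_loglog(ser$concentration_g_L, ser$da_pct,
                           model_form = "relative_vs_concentration",
                           endpoint = endpoint)
    rows <- rbind(rows, data.frame(model_form = "relative_vs_concentration",
                                   slope = conc_fit$slope, r2 = conc_fit$r2,
                                   aic = conc_fit$aic, n = conc_fit$n,
                                   stringsAsFactors = FALSE))
  }
  attr(rows, "different_response") <- nrow(rows) == 2L
  rows
}

#' Fit log-log models within strata
#'
#' Splits the endpoint series by one or more grouping columns (for example
#' per product, per preparation, per test system or per observation time)
#' and fits one log-log model per stratum. Strata with fewer than two usable
#' records are skipped with a warning.
#'
#' @param table A [study_table()].
#' @param by Character vector of grouping columns, a subset of
#'   `c("preparation", "formulation_code", "test_system",
#'   "observation_time_h", "product_id")`.
#' @param model_form,endpoint As in [fit_loglog()].
#' @return A named list of `loglog_fit` objects (class `loglog_fit_list`),
#'   named by stratum label.
#' @export
stratified_fits <- function(table, by = "product_id",
                            model_form = c("absolute_vs_dose",
                                           "relative_vs_concentration"),
                            endpoint = c("RF", "POT")) {
  model_form <- match.arg(model_form)
  endpoint <- match.arg(endpoint)
  allowed <- c("preparation", "formulation_code", "test_system",
               "observation_time_h", "product_id")
  if (!length(by) || !all(by %in% allowed)) {
    stop("'by' must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  ser <- endpoint_series(table, endpoint)
  key <- interaction(ser[by], drop = TRUE, sep = "/")
  fits <- list()
  for (lev in levels(key)) {
    sub <- ser[key == lev, , drop = FALSE]
    d <- if (model_form == "absolute_vs_dose") {
      list(x = sub$applied, y = sub$absorbed)
    } else {
      list(x = sub$concentration_g_L, y = sub$da_pct)
    }
    ok <- sum(!is.na(d$x) & !is.na(d$y) & d$x > 0 & d$y > 0)
    if (ok < 2L) {
      warning("stratum '", lev, "' skipped: ", ok, " usable record(s)",
              call. = FALSE)
      next
    }
    fits[[lev]] <- fit_loglog(d$x, d$y, model_form = model_form,
                              endpoint = endpoint, stratum = lev)
  }
  if (length(fits) == 0L) {
    stop("insufficient data: no stratum retained >= 2 usable records",
         call. = FALSE)
  }
  class(fits) <- "loglog_fit_list"
  fits
}

#' @export
print.loglog_fit_list <- function(x, ...) {
  cat("Stratified log-log fits (", length(x), " strata)\n", sep = "")
  print(fits_to_df(x), digits = 4)
  invisible(x)
}

#' Flatten fits to a data.frame
#'
#' One row per fit: stratum, model form, endpoint, slope, its SE and
#' confidence interval, intercept, R2, AIC, n. Suitable for CSV or JSON
#' export.
#'
#' @param fits A single `loglog_fit` or a `loglog_fit_list`.
#' @param level Confidence level for the slope interval (fits with `n < 3`
#'   get `NA` bounds).
#' @return A data.frame.
#' @export
fits_to_df <- function(fits, level = 0.95) {
  if (inherits(fits, "loglog_fit")) fits <- structure(list(fits))
  rows <- lapply(fits, function(f) {
    ci <- if (f$n >= 3L) slope_ci(f, level) else c(lo = NA_real_, hi = NA_real_)
    data.frame(stratum = f$stratum, model_form = f$model_form,
               endpoint = f$endpoint, slope = f$slope, se_slope = f$se_slope,
               ci_lo = unname(ci[1L]), ci_hi = unname(ci[2L]),
               intercept = f$intercept, r2 = f$r2, aic = f$aic, n = f$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ci_level") <- level
  out
}
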