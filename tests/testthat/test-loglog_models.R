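test_that("log-log fits reproduce the worked-example slopes", {
  ex <- example_products()
  fit_fmc <- fit_loglog(ex$FMC_P2_CS$applied,
                        relative_to_absolute(ex$FMC_P2_CS$applied,
                                             ex$FMC_P2_CS$da_pct))
  expect_equal(round(fit_fmc$slope, 3), 0.227)
  fit_syn <- fit_loglog(ex$SYN_P10_SC$applied,
                        relative_to_absolute(ex$SYN_P10_SC$applied,
                                             ex$SYN_P10_SC$da_pct))
  expect_equal(round(fit_syn$slope, 2), 1.56)
})

test_that("an exact power law is recovered perfectly", {
  x <- c(1, 3, 10, 42, 100)
  y <- 10 * x^0.5
  fit <- fit_loglog(x, y)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$se_slope, 0, tolerance = 1e-12)
  expect_equal(model_aic(fit), -Inf)  # RSS = 0 sentinel
})

test_that("OLS equals the brute-force normal-equations solution", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- 10^runif(n, -1, 2)
    y <- 10^(runif(1, -2, 0) + runif(1, 0, 1.5) * log10(x) + rnorm(n, 0, 0.3))
    fit <- fit_loglog(x, y)
    o <- ols_bruteforce(log10(x), log10(y))
    expect_equal(fit$slope, o$slope)
    expect_equal(fit$intercept, o$intercept)
    expect_equal(fit$se_slope, o$se_slope)
    expect_equal(fit$se_intercept, o$se_intercept)
    expect_equal(fit$r2, o$r2)
  }
})

test_that("log-domain filtering and degenerate designs error or warn", {
  expect_warning(fit <- fit_loglog(c(1, 2, 4, 8), c(1, 0, 2, 4)),
                 "non-positive")
  expect_equal(fit$n, 3L)
  expect_error(suppressWarnings(fit_loglog(c(1, 2), c(0, 0))),
               "insufficient data")
  expect_error(fit_loglog(c(5, 5, 5), c(1, 2, 3)), "singular design")
  # optional limit-of-quantification floor keeps the record
  flo <- fit_loglog(c(1, 2, 4, 8), c(1, 0.01, 2, 4), floor = 0.01)
  expect_equal(flo$n, 4L)
})

test_that("slope CI is a two-sided t-interval and nests by level", {
  set.seed(11)
  x <- 10^seq(0, 2, length.out = 10)
  y <- 10^(-1 + log10(x) + rnorm(10, 0, 0.2))
  fit <- fit_loglog(x, y)
  o <- ols_bruteforce(log10(x), log10(y))
  tq <- qt(0.975, df = 8)
  expect_equal(unname(slope_ci(fit, 0.95)),
               c(o$slope - tq * o$se_slope, o$slope + tq * o$se_slope))
  ci80 <- slope_ci(fit, 0.80)
  ci95 <- slope_ci(fit, 0.95)
  expect_true(ci95[1] < ci80[1] && ci80[2] < ci95[2])
  # zero-width at a perfect fit
  pf <- fit_loglog(c(1, 10, 100), c(2, 20, 200))
  expect_equal(unname(slope_ci(pf, 0.95)), c(1, 1))
  # n = 2 leaves no residual degrees of freedom
  expect_error(slope_ci(fit_loglog(c(1, 10), c(1, 5))), "degrees-of-freedom")
})

test_that("AIC follows the full Gaussian ML convention", {
  set.seed(12)
  x <- 10^runif(8, 0, 2)
  y <- 10^(0.5 + 0.8 * log10(x) + rnorm(8, 0, 0.25))
  fit <- fit_loglog(x, y)
  expect_equal(fit$aic, aic_bruteforce(x, y))
  # and matches stats::AIC on the equivalent lm
  expect_equal(fit$aic, AIC(lm(log10(y) ~ log10(x))))
  # delta-AIC invariant to shifting all log responses by a constant
  fit2 <- fit_loglog(x, y * 10)
  set.seed(13)
  y3 <- 10^(0.1 + 0.3 * log10(x) + rnorm(8, 0, 0.4))
  fit3 <- fit_loglog(x, y3)
  fit4 <- fit_loglog(x, y3 * 10)
  expect_equal(fit$aic - fit3$aic, fit2$aic - fit4$aic)
  # duplicating rows changes AIC but not the slope
  dup <- fit_loglog(c(x, x), c(y, y))
  expect_equal(dup$slope, fit$slope)
  expect_false(isTRUE(all.equal(dup$aic, fit$aic)))
})

test_that("r2 of a refit on its own fitted values is 1", {
  set.seed(14)
  x <- 10^runif(6, 0, 2)
  y <- 10^(-1 + 0.9 * log10(x) + rnorm(6, 0, 0.3))
  fit <- fit_loglog(x, y)
  yhat <- 10^(fit$intercept + fit$slope * log10(x))
  expect_equal(fit_loglog(x, yhat)$r2, 1)
})

test_that("mixed model recovers the no-heterogeneity limit and R2 identities", {
  cfg <- generator_config(n_products = 6, seed = 202, sigma_resid = 0.1,
                          tau_product = 0)
  tab <- generate_study(cfg)
  mf <- fit_mixed(tab)
  # tau^2 = 0 truth: the estimated product variance is a negligible share
  expect_lt(mf$var_random / (mf$var_fixed + mf$var_random + mf$var_resid),
            0.02)
  expect_equal(mf$r2_marginal, mf$r2_conditional, tolerance = 0.03)
  expect_lte(mf$r2_marginal, mf$r2_conditional)
  # stated variance decomposition: (1, 1, 2) -> 0.25 / 0.50
  tot <- 1 + 1 + 2
  expect_equal(1 / tot, 0.25)
  expect_equal((1 + 1) / tot, 0.50)
  expect_equal(mf$r2_marginal,
               mf$var_fixed / (mf$var_fixed + mf$var_random + mf$var_resid))
  expect_equal(mf$r2_conditional,
               (mf$var_fixed + mf$var_random) /
                 (mf$var_fixed + mf$var_random + mf$var_resid))
})

test_that("mixed fit converges to the simple fit on noiseless data", {
  cfg <- generator_config(n_products = 5, seed = 303, sigma_resid = 0,
                          tau_product = 0)
  tab <- generate_study(cfg)
  simple <- fit_loglog(tab$applied_dose_ug_cm2,
                       relative_to_absolute(tab$applied_dose_ug_cm2,
                                            tab$rf_pct))
  # zero-variance data trips lmer's convergence checks; estimates are exact
  mf <- suppressWarnings(fit_mixed(tab))
  expect_equal(mf$slope, simple$slope, tolerance = 1e-6)
  expect_equal(mf$intercept, simple$intercept, tolerance = 1e-6)
})

test_that("a single product is a degenerate grouping for the mixed model", {
  cfg <- generator_config(n_products = 1, seed = 404)
  tab <- generate_study(cfg)
  expect_error(fit_mixed(tab), "degenerate grouping.*fit_loglog")
})

test_that("model-form comparison reports both forms and flags the responses", {
  tab <- example_study()
  cmp <- compare_model_forms(tab)
  expect_equal(cmp$model_form,
               c("absolute_vs_dose", "relative_vs_concentration"))
  expect_true(attr(cmp, "different_response"))
  # constant DA% at all doses: dose-form slope 1, concentration-form slope 0
  const <- study_table(data.frame(
    product_id = "P1", preparation = "dilution",
    applied_dose_ug_cm2 = c(10, 30, 100),
    concentration_g_L = c(1, 3, 10), rf_pct = 5))
  cmp2 <- compare_model_forms(const)
  expect_equal(cmp2$slope[cmp2$model_form == "absolute_vs_dose"], 1)
  expect_equal(cmp2$slope[cmp2$model_form == "relative_vs_concentration"], 0,
               tolerance = 1e-12)
  # missing concentrations: dose-form row only, with a warning
  noconc <- example_study_df()
  noconc$concentration_g_L <- NA_real_
  expect_warning(cmp3 <- compare_model_forms(study_table(noconc)),
                 "dose-form")
  expect_equal(nrow(cmp3), 1L)
})

test_that("stratified fits label strata and skip undersized ones", {
  tab <- example_study()
  fits <- stratified_fits(tab, by = "product_id")
  expect_named(fits, c("BAY_P6_WG", "FMC_P2_CS", "SYN_P10_SC"),
               ignore.order = TRUE)
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  expect_equal(round(unname(slopes[c("FMC_P2_CS", "BAY_P6_WG", "SYN_P10_SC")]),
                     3),
               c(0.227, 0.987, 1.559))
  # two preparations -> two labelled fits
  df <- example_study_df()
  df$preparation[df$product_id == "SYN_P10_SC"] <- "concentrate"
  fits2 <- stratified_fits(study_table(df), by = "preparation")
  expect_named(fits2, c("concentrate", "dilution"), ignore.order = TRUE)
  # stratum with one record is skipped with a warning
  df2 <- example_study_df()[c(1:4, 5), ]
  expect_warning(fits3 <- stratified_fits(study_table(df2),
                                          by = "product_id"),
                 "skipped")
  expect_named(fits3, "FMC_P2_CS")
  expect_error(suppressWarnings(stratified_fits(study_table(df2[5, ]),
                                                by = "product_id")),
               "insufficient data")
})

test_that("fit export table carries CI bounds and metadata", {
  fits <- stratified_fits(example_study(), by = "product_id")
  fdf <- fits_to_df(fits, level = 0.95)
  expect_equal(nrow(fdf), 3L)
  expect_true(all(c("stratum", "slope", "ci_lo", "ci_hi", "aic", "n") %in%
                    names(fdf)))
  expect_true(all(fdf$ci_lo <= fdf$slope & fdf$slope <= fdf$ci_hi))
})
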