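# Shared fixtures: the three published-style worked-example studies with
# multiple tested in-use dilution concentrations, and small builders for
# ad-hoc tables. All fixtures are constructed in code.

example_products <- function() {
  list(
    FMC_P2_CS = list(applied = c(62.37, 31.43, 22.71, 16.45),
                     da_pct = c(5.2, 8.93, 12.54, 13.96)),
    BAY_P6_WG = list(applied = c(29.7, 14.8, 8.8),
                     da_pct = c(1.32, 1.8, 1.3)),
    SYN_P10_SC = list(applied = c(49.8, 26.2, 16.5),
                      da_pct = c(2.54, 3.0, 1.29))
  )
}

example_study_df <- function() {
  ex <- example_products()
  do.call(rbind, lapply(names(ex), function(p) {
    data.frame(product_id = p,
               active_id = sub("_P.*", "_A", p),
               formulation_code = sub(".*_", "", p),
               test_system = "in_vitro_human",
               preparation = "dilution",
               applied_dose_ug_cm2 = ex[[p]]$applied,
               concentration_g_L = ex[[p]]$applied / 10,  # 10 uL/cm2 volume
               observation_time_h = 24,
               rf_pct = ex[[p]]$da_pct,
               skin_pct = NA_real_,
               ts12_pct = NA_real_,
               stringsAsFactors = FALSE)
  }))
}

example_study <- function() study_table(example_study_df(), "worked examples")

write_example_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(example_study_df(), path, row.names = FALSE, na = "")
  path
}

# Independent OLS oracle: closed-form normal equations, no lm().
ols_bruteforce <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  s2 <- rss / (n - 2)
  list(slope = slope, intercept = intercept, rss = rss,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mx^2 / sxx)),
       r2 = 1 - rss / sum((y - my)^2))
}

# Independent Gaussian log-likelihood oracle for the AIC convention.
aic_bruteforce <- function(x, y) {
  o <- ols_bruteforce(log10(x), log10(y))
  n <- length(x)
  sigma2_ml <- o$rss / n
  fitted <- o$intercept + o$slope * log10(x)
  ll <- sum(stats::dnorm(log10(y), fitted, sqrt(sigma2_ml), log = TRUE))
  -2 * ll + 2 * 3
}
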