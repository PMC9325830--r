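# Synthetic study generator.
#
# Emulates the structure of regulatory dermal absorption databases: each
# product is tested at >= 3 in-use dilution concentrations, the applied dose
# is coupled to concentration through a fixed application volume
# (D [ug/cm2] = volume [uL/cm2] * c [g/L], since 1 g/L = 1 ug/uL), and the
# absorbed dose follows a log-log line with lognormal residual noise and a
# lognormal product-level random intercept:
#   log10 A = intercept + u_p + slope * log10 D + eps,
#   u_p ~ N(0, tau^2), eps ~ N(0, sigma^2).

#' Configuration for the synthetic study generator
#'
#' @param n_products Number of products to simulate.
#' @param concentrations_g_L Concentrations of the test preparation tested
#'   per product, g a.i./L; at least 3, mirroring study programmes with
#'   multiple in-use dilutions. The default spans two orders of magnitude.
#' @param application_volume_uL_cm2 Fixed application volume; default 10
#'   uL/cm2, the conventional droplet-exposure volume.
#' @param true_slope Slope of the generating log-log line; 1 = direct dose
#'   proportionality.
#' @param true_intercept Intercept in log10 units; the default -1.65
#'   corresponds to a typical receptor-fluid average of about 2.2%.
#' @param sigma_resid Residual SD on the log10 scale.
#' @param tau_product SD of the product-level random intercept (log10 scale).
#' @param seed Integer seed (required; generation is fully reproducible).
#' @param formulation_codes Labels recycled over products (e.g. `"SC"`,
#'   `"WG"`, `"EC"`).
#' @param preparation `"dilution"` (default) or `"concentrate"`.
#' @param test_system Test system label for all records.
#' @param observation_time_h Observation time recorded for all groups.
#' @param volume_jitter Relative half-width of uniform per-group jitter on
#'   the application volume (0 = exactly fixed volume, giving a perfect
#'   dose-concentration correlation; 0.2 = +/-20%).
#' @param volume_log10_sd SD of a lognormal per-group spread of the
#'   application volume on the log10 scale (default 0). Non-zero values
#'   emulate heterogeneous database collections where applied doses span
#'   several orders of magnitude independently of concentration, rather
#'   than a single harmonised protocol.
#' @param product_prefix Prefix for generated product ids.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_products = 10,
                             concentrations_g_L = 10^seq(-1, 1, length.out = 4),
                             application_volume_uL_cm2 = 10,
                             true_slope = 1,
                             true_intercept = -1.65,
                             sigma_resid = 0.2,
                             tau_product = 0.3,
                             seed,
                             formulation_codes = "SC",
                             preparation = c("dilution", "concentrate"),
                             test_system = "in_vitro_human",
                             observation_time_h = 24,
                             volume_jitter = 0,
                             volume_log10_sd = 0,
                             product_prefix = "SIM_P") {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  preparation <- match.arg(preparation)
  stopifnot(n_products >= 1, length(concentrations_g_L) >= 3,
            all(concentrations_g_L > 0), application_volume_uL_cm2 > 0,
            sigma_resid >= 0, tau_product >= 0,
            volume_jitter >= 0, volume_jitter < 1, volume_log10_sd >= 0)
  structure(list(n_products = as.integer(n_products),
                 concentrations_g_L = concentrations_g_L,
                 application_volume_uL_cm2 = application_volume_uL_cm2,
                 true_slope = true_slope,
                 true_intercept = true_intercept,
                 sigma_resid = sigma_resid,
                 tau_product = tau_product,
                 seed = as.integer(seed),
                 formulation_codes = formulation_codes,
                 preparation = preparation,
                 test_system = test_system,
                 observation_time_h = observation_time_h,
                 volume_jitter = volume_jitter,
                 volume_log10_sd = volume_log10_sd,
                 product_prefix = product_prefix),
            class = "generator_config")
}

#' Generate a synthetic study table
#'
#' One record per product x concentration. The relative recovery
#' `rf_pct = 100 * A / D` must land in (0, 100]; draws exceeding 100% are
#' rejection-resampled (rather than truncated, to keep the log-scale noise
#' approximately Gaussian) and the number of resamples is reported in the
#' `n_resampled` attribute with a warning.
#'
#' @param config A [generator_config()].
#' @return A [study_table()] with attribute `n_resampled`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    resampled <- 0L
    rows <- list()
    codes <- rep_len(cf$formulation_codes, cf$n_products)
    width <- max(2L, nchar(as.character(cf$n_products)))
    for (p in seq_len(cf$n_products)) {
      u_p <- stats::rnorm(1L, 0, cf$tau_product)
      for (conc in cf$concentrations_g_L) {
        vol <- cf$application_volume_uL_cm2
        if (cf$volume_log10_sd > 0) {
          vol <- vol * 10^stats::rnorm(1L, 0, cf$volume_log10_sd)
        }
        if (cf$volume_jitter > 0) {
          vol <- vol * (1 + stats::runif(1L, -cf$volume_jitter,
                                         cf$volume_jitter))
        }
        dose <- vol * conc  # 1 g/L = 1 ug/uL
        repeat {
          eps <- stats::rnorm(1L, 0, cf$sigma_resid)
          la <- cf$true_intercept + u_p + cf$true_slope * log10(dose) + eps
          rf <- 100 * 10^la / dose
          if (rf <= 100) break
          resampled <- resampled + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          product_id = sprintf("%s%0*d", cf$product_prefix, width, p),
          active_id = sprintf("%sA%0*d", cf$product_prefix, width, p),
          formulation_code = codes[p],
          test_system = cf$test_system,
          preparation = cf$preparation,
          applied_dose_ug_cm2 = dose,
          concentration_g_L = conc,
          observation_time_h = cf$observation_time_h,
          rf_pct = rf,
          skin_pct = NA_real_,
          ts12_pct = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    tab <- study_table(do.call(rbind, rows),
                       provenance = sprintf("synthetic (seed %d)", cf$seed))
    if (resampled > 0L) {
      warning(resampled, " draw(s) exceeded 100% recovery and were resampled",
              call. = FALSE)
    }
    attr(tab, "n_resampled") <- resampled
    tab
  })
}

#' Correlation of log10 dose and log10 concentration
#'
#' Pearson correlation on the decadic log scale. With a fixed application
#' volume the applied dose is proportional to concentration and the
#' correlation is exactly 1; jittered volumes reduce it slightly, as in real
#' study collections where applied volumes vary a little around the nominal
#' value.
#'
#' @param table A [study_table()] with both dose and concentration populated.
#' @return Pearson r.
#' @export
dose_concentration_correlation <- function(table) {
  d <- table$applied_dose_ug_cm2
  cc <- table$concentration_g_L
  keep <- !is.na(d) & !is.na(cc)
  d <- d[keep]; cc <- cc[keep]
  if (length(d) < 2L) stop("need >= 2 records with dose and concentration",
                           call. = FALSE)
  if (stats::sd(log10(d)) == 0 || stats::sd(log10(cc)) == 0) {
    stop("undefined correlation: a column is constant on the log scale",
         call. = FALSE)
  }
  stats::cor(log10(d), log10(cc))
}

#' Generate a database-like table from several configurations
#'
#' Concatenates [generate_study()] output across configurations, e.g. to mix
#' formulation types and preparations into a single database-style table with
#' concentrate/dilution strata. Product ids are disambiguated per
#' configuration.
#'
#' @param configs A non-empty list of [generator_config()] objects.
#' @return A [study_table()] with attribute `n_resampled` (total).
#' @export
generate_database <- function(configs) {
  if (!is.list(configs) || length(configs) == 0L ||
      !all(vapply(configs, inherits, logical(1L), "generator_config"))) {
    stop("configs must be a non-empty list of generator_config objects",
         call. = FALSE)
  }
  parts <- vector("list", length(configs))
  resampled <- 0L
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    if (length(configs) > 1L) {
      cf$product_prefix <- sprintf("%sC%d_", cf$product_prefix, i)
    }
    tab <- generate_study(cf)
    resampled <- resampled + attr(tab, "n_resampled")
    parts[[i]] <- as.data.frame(tab)
  }
  out <- study_table(do.call(rbind, parts),
                     provenance = sprintf("synthetic database (%d configs)",
                                          length(configs)))
  attr(out, "n_resampled") <- resampled
  out
}
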