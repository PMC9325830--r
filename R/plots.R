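# Isoslope diagnostic plot: absorbed vs applied dose on log10-log10 axes.

#' Isoslope plot of absorbed against applied dose
#'
#' Log10-log10 scatter of the absolute absorbed dose against the applied
#' dose (both ug/cm2). The solid black line is the identity (100% relative
#' absorption); dotted lines with the same unit slope ("isoslopes") sit at
#' tenfold spacings below it and mark 10, 1 and 0.1% relative absorption. A
#' fitted line parallel to the isoslopes means relative absorption is
#' constant across doses, and its height gives the average absorption value;
#' a non-parallel line means relative absorption changes with dose. Fitted
#' models are over-plotted per stratum.
#'
#' @param table A [study_table()].
#' @param fits Optional `loglog_fit_list` (or single `loglog_fit`) of
#'   `absolute_vs_dose` fits to over-plot; `NULL` for a scatter-only figure.
#' @param endpoint `"RF"` or `"POT"`.
#' @param path Optional output path; the extension selects the device
#'   (`.png`, `.svg`, `.pdf`).
#' @param width,height Figure size in inches when writing to file.
#' @return The ggplot object, invisibly when written to file.
#' @export
isoslope_plot <- function(table, fits = NULL, endpoint = c("RF", "POT"),
                          path = NULL, width = 7, height = 5) {
  endpoint <- match.arg(endpoint)
  ser <- endpoint_series(table, endpoint)
  ser <- ser[ser$applied > 0 & ser$absorbed > 0, , drop = FALSE]
  if (nrow(ser) == 0L) stop("no positive (applied, absorbed) points to plot",
                            call. = FALSE)
  iso <- data.frame(intercept = c(-1, -2, -3),
                    label = c("10%", "1%", "0.1%"))
  p <- ggplot2::ggplot(ser, ggplot2::aes(x = log10(.data$applied),
                                         y = log10(.data$absorbed))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.5) +
    ggplot2::geom_abline(data = iso,
                         ggplot2::aes(slope = 1, intercept = .data$intercept),
                         linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$product_id)) +
    ggplot2::labs(
      x = expression(log[10] ~ "applied dose (" * mu * "g/cm"^2 * ")"),
      y = expression(log[10] ~ "absorbed dose (" * mu * "g/cm"^2 * ")"),
      colour = "product",
      title = sprintf("Isoslope plot (%s endpoint)", endpoint),
      subtitle = "solid: identity (100%); dotted: 10 / 1 / 0.1% isoslopes") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    fd <- fits_to_df(fits)
    fd <- fd[fd$model_form == "absolute_vs_dose", , drop = FALSE]
    if (nrow(fd) > 0L) {
      p <- p + ggplot2::geom_abline(
        data = fd,
        ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                     colour = .data$stratum),
        linewidth = 0.6)
    }
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
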