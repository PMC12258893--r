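#' Plot desilencing trajectories
#'
#' Mean percent-GFP-positive per generation with SD error bars, one line
#' per strain, faceted by block (and environment when several are
#' present).
#'
#' @param summary A [trajectory_summary()] tibble.
#' @param axis `"generations"` or `"days"` for the x coordinate.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(summary, axis = c("generations", "days")) {
  axis <- match.arg(axis)
  xvar <- if (axis == "generations") "generation" else "day"
  p <- ggplot2::ggplot(summary, ggplot2::aes(
    x = .data[[xvar]], y = .data$mean_pct, colour = .data$strain,
    group = interaction(summary$strain, summary$environment))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_pct - .data$sd_pct, 0),
      ymax = pmin(.data$mean_pct + .data$sd_pct, 100)), width = 0.15) +
    ggplot2::labs(x = if (axis == "generations")
      "generations after trigger removal" else "days after trigger removal",
      y = "% GFP-positive individuals", colour = "strain") +
    ggplot2::theme_bw()
  if (length(unique(summary$environment)) > 1) {
    p + ggplot2::facet_grid(environment ~ block)
  } else {
    p + ggplot2::facet_wrap(~block)
  }
}

#' Boxplot of half-life estimates
#'
#' One box per strain (optionally split by environment) of the
#' non-censored half-life values across blocks and replicates.
#'
#' @param halflife A [half_life_table()] tibble.
#' @return A ggplot object.
#' @export
plot_halflife <- function(halflife) {
  ok <- halflife[halflife$status != "censored", , drop = FALSE]
  axis <- unique(ok$axis)
  p <- ggplot2::ggplot(ok, ggplot2::aes(
    x = .data$strain, y = .data$value, fill = .data$strain)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = NULL,
                  y = sprintf("half-life of silencing memory (%s)", axis)) +
    ggplot2::theme_bw()
  if (length(unique(ok$environment)) > 1) {
    p + ggplot2::facet_wrap(~environment)
  } else {
    p
  }
}
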