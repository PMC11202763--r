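# Learning-curve and trace plots over aggregated experiment metrics.

#' Plot per-episode learning curves with dispersion bands
#'
#' Draws the across-seed mean of a metric per episode, with a ribbon of
#' plus/minus one standard error (or standard deviation / interquartile
#' range), one curve per agent.  Requires ggplot2.
#'
#' @param metrics Data frame from [run_experiment()], possibly several
#'   row-bound together.
#' @param var Metric column: `"length"`, `"score"`, `"mean_gamma"` or
#'   `"mean_beta"`.
#' @param band Dispersion band: `"sem"`, `"sd"` or `"iqr"`.
#' @param final_window Passed to [aggregate_metrics()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(metrics, var = "length",
                                band = c("sem", "sd", "iqr"),
                                final_window = 50L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_learning_curve: ggplot2 is not installed")
  band <- match.arg(band)
  agg <- aggregate_metrics(metrics, final_window = final_window)$per_episode
  mu <- agg[[paste0(var, "_mean")]]
  if (band == "iqr") {
    lo <- agg[[paste0(var, "_q25")]]
    hi <- agg[[paste0(var, "_q75")]]
  } else {
    half <- agg[[paste0(var, "_", band)]]
    lo <- mu - half
    hi <- mu + half
  }
  d <- data.frame(agent = agg$agent, episode = agg$episode,
                  mu = mu, lo = lo, hi = hi)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$episode, y = .data$mu,
                                  colour = .data$agent,
                                  fill = .data$agent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = var) +
    ggplot2::theme_minimal()
}
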