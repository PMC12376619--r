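#' Catalog growth curve plot
#'
#' Cumulative nonredundant SV count as samples are added in merge order.
#'
#' @param growth tibble from [cumulative_growth()].
#' @return a ggplot.
#' @export
plot_growth_curve <- function(growth) {
  growth$idx <- seq_len(nrow(growth))
  ggplot2::ggplot(growth, ggplot2::aes(x = .data$idx,
                                       y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "samples added", y = "nonredundant SVs",
                  title = "Cumulative SV catalog growth") +
    ggplot2::theme_minimal()
}

#' @rdname di_statistic
#' @param alpha significance level drawn as the outlier threshold.
#' @method autoplot svalt_di
#' @export
autoplot.svalt_di <- function(object, alpha = 0.001, ...) {
  df <- object$di
  thr <- mean(df$di, na.rm = TRUE) +
    qnorm(1 - alpha) * sd(df$di, na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$di)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$focal)) +
    ggplot2::labs(x = "di", y = "SVs",
                  title = "di distribution with one-sided outlier threshold") +
    ggplot2::theme_minimal()
}

#' @rdname call_hotspots
#' @method autoplot svalt_hotspots
#' @export
autoplot.svalt_hotspots <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$chrom,
                                       yend = .data$chrom,
                                       colour = .data$n_sv),
                          linewidth = 4) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "SVs",
                  title = "SV hotspot intervals") +
    ggplot2::theme_minimal()
}

#' @rdname enrichment_z
#' @param object an `svalt_enrichment` object.
#' @method autoplot svalt_enrichment
#' @export
autoplot.svalt_enrichment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_col(ggplot2::aes(x = "null", y = .data$null_mean),
                      fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      x = "null", ymin = .data$null_mean - .data$null_sd,
      ymax = .data$null_mean + .data$null_sd), width = 0.2) +
    ggplot2::geom_col(ggplot2::aes(x = "observed", y = .data$observed),
                      fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "annotated points in hotspots",
                  title = sprintf("Enrichment Z = %.2f (%s)", df$z,
                                  df$direction)) +
    ggplot2::theme_minimal()
}
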