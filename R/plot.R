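# Health-vs-density scatter with per-group fitted lines.

#' Plot health against microbial density with per-group fitted lines
#'
#' Scatter of the outcome against density on the analysis scale, coloured by
#' group, with each group's least-squares line (or logistic curve for binary
#' outcomes) overlaid.
#'
#' @inheritParams test_density_variation
#' @return a ggplot object.
#' @export
plot_health_density <- function(records, grouping = c("host_type", "strain"),
                                scale = c("log10p1", "raw"),
                                include_uninfected = TRUE) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  df <- prep$df
  xlab <- if (scale == "log10p1") "microbial density (log10 cfu + 1)" else "microbial density (cfu)"
  ylab <- if (prep$outcome_kind == "binary") "survival" else "health"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$outcome,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = xlab, y = ylab, colour = grouping) +
    ggplot2::theme_minimal()
  if (prep$outcome_kind == "binary") {
    p + ggplot2::geom_smooth(method = "glm", formula = y ~ x, se = FALSE,
                             method.args = list(family = stats::binomial()))
  } else {
    p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE)
  }
}
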