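# Optional chart rendering. Plotting is deliberately not a hard
# dependency: the CSV exports are the primary artifact, and ggplot2 is
# only loaded when a plot is actually requested.

#' Plot a control chart
#'
#' Observed per-period rates with the center line, stepped control
#' limits, and rule-1 signal markers. Requires ggplot2 (Suggests).
#'
#' @param chart A `control_chart`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_chart <- function(chart, title = NULL) {
  stopifnot(inherits(chart, "control_chart"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  p <- chart$periods
  p$idx <- seq_len(nrow(p))
  p$flagged <- p$period_id %in%
    chart$signals$period_id[chart$signals$rule_id == "rule_1"]
  if (is.null(title)) {
    title <- sprintf("%s (sigma_z %s)", chart$chart_type,
      ifelse(is.na(chart$sigma_z), "-", sprintf("%.2f", chart$sigma_z))
    )
  }
  ggplot2::ggplot(p, ggplot2::aes(x = .data$idx, y = .data$u)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ucl),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lcl),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::geom_hline(yintercept = chart$center, colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      guide = "none"
    ) +
    ggplot2::labs(
      title = title, x = "period", y = "events per exposure unit"
    ) +
    ggplot2::theme_minimal()
}
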