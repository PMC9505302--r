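#' Step plot of cumulative incidence curves
#'
#' @param object A `cif_tbl` from [cumulative_incidence()].
#' @param ... Unused.
#' @return A ggplot object: one step curve per group, starting at
#'   CIF(0) = 0.
#' @method autoplot cif_tbl
#' @export
autoplot.cif_tbl <- function(object, ...) {
  endpoint <- attr(object, "endpoint")
  origin <- object |>
    group_by(.data$group) |>
    summarise(time = 0, estimate = 0, .groups = "drop")
  dat <- bind_rows(origin,
                   object |> select("group", "time", "estimate"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$estimate,
                                    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since DLI",
                  y = sprintf("Cumulative incidence of %s", endpoint),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diversity trajectories over time
#'
#' Plots per-subject inverse Simpson diversity against sampling day, with
#' the healthy-control interquartile band (p25-p75 of the reference) shaded
#' when a reference is supplied.
#'
#' @param df A metrics tibble (e.g. from [repertoire_metrics()]) with
#'   columns `subject_id`, `timepoint` and the metric named by `value`.
#' @param reference Optional [hc_reference][build_hc_reference()] object.
#' @param value Metric column (default `"inv_simpson"`).
#' @return A ggplot object.
#' @export
plot_diversity_trajectories <- function(df, reference = NULL,
                                        value = "inv_simpson") {
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint,
                                        y = .data[[value]],
                                        group = .data$subject_id,
                                        colour = .data$subject_id))
  if (!is.null(reference)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = reference$p25, ymax = reference$p75,
                               alpha = 0.15, fill = "steelblue")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Day", y = "Inverse Simpson diversity (1/D)",
                  colour = "Subject") +
    ggplot2::theme_minimal()
}
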