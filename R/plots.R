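# ggplot2 renderings of the analytics tables. Every plot is a thin layer
# over a tidy table the package also exports, so numbers are always
# available without graphics.

#' Plot a recovery curve
#'
#' Score-vs-rank curve with its 95% band; vertical bars mark the active
#' placements (solid: rank of mean scores; dashed: mean of per-replica
#' ranks) with their rank confidence intervals shaded.
#'
#' @param object A `recovery_curve` from [score_band()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  act <- curve_actives(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "rank", y = attr(object, "metric"),
                  title = sprintf("Recovery: %s (%s replicas, %s interval)",
                                  attr(object, "metric"),
                                  attr(object, "n_replicas"),
                                  attr(object, "ci"))) +
    ggplot2::theme_minimal()
  if (nrow(act)) {
    p <- p +
      ggplot2::geom_rect(data = act,
                         ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                         ymin = -Inf, ymax = Inf, fill = "firebrick",
                         alpha = 0.15, inherit.aes = FALSE) +
      ggplot2::geom_vline(data = act,
                          ggplot2::aes(xintercept = .data$mean_of_ranks),
                          colour = "firebrick", linewidth = 0.5) +
      ggplot2::geom_vline(data = act,
                          ggplot2::aes(xintercept = .data$rank_of_means),
                          colour = "firebrick", linetype = "dashed",
                          linewidth = 0.4)
  }
  p
}

#' Violin plot of active ranks per metric
#'
#' The replica ranks of every labeled binder, one violin per metric, with
#' the median dot and interquartile bar.
#'
#' @param scores A long score table.
#' @param metrics Character vector of metric names to include.
#' @param labels Labels data frame (`pair_id`, `label`); defaults to a
#'   `label` column of `scores`.
#' @param registry Metric registry.
#' @return A ggplot object.
#' @export
plot_rank_violins <- function(scores, metrics, labels = NULL,
                              registry = metric_registry()) {
  labels <- resolve_labels(scores, labels)
  binders <- labels$pair_id[labels$label == "binder"]
  long <- purrr::map_dfr(metrics, function(mt) {
    reps <- sort(unique(scores$replica[scores$metric == mt &
                                         !is.na(scores$value)]))
    purrr::map_dfr(reps, function(r) {
      rk <- rank_by_metric(scores, mt, r, registry)
      tibble::as_tibble(rk) |>
        dplyr::filter(.data$pair_id %in% binders) |>
        dplyr::mutate(metric = mt, replica = r)
    })
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$rank)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::stat_summary(fun.min = function(v) stats::quantile(v, 0.25),
                          fun.max = function(v) stats::quantile(v, 0.75),
                          geom = "linerange", linewidth = 1.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 2,
                          colour = "white", fill = "white", shape = 21) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "active rank (lower is earlier)") +
    ggplot2::theme_minimal()
}

#' Plot rank confidence intervals
#'
#' @param intervals A tibble from [rank_confidence()].
#' @return A ggplot object.
#' @export
plot_rank_intervals <- function(intervals) {
  df <- intervals[intervals$note == "", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point,
                                   y = stats::reorder(.data$pair_id,
                                                      -.data$point))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "rank (95% interval)", y = NULL) +
    ggplot2::theme_minimal()
}
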