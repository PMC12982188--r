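# Rankings: sorting pairs by a metric, single replica or aggregated.
#
# Rank 1 is always the best score in the metric's declared direction; ties
# break by pair id lexicographically so every ranking is reproducible. Pairs
# without a value under the requested metric/replica are excluded (N' <= N)
# and surfaced in the attached completeness report — no imputation.

new_ranking <- function(df, metric, direction, aggregation, missing_pairs) {
  structure(
    df,
    class = c("ranking", "tbl_df", "tbl", "data.frame"),
    metric = metric, direction = direction, aggregation = aggregation,
    missing_pairs = missing_pairs
  )
}

rank_values <- function(pair_id, value, direction) {
  key <- if (direction == "lower") value else -value
  ord <- order(key, pair_id)
  tibble::tibble(pair_id = pair_id[ord], value = value[ord],
                 rank = seq_along(ord))
}

#' Rank pairs by one metric in a single replica
#'
#' @param scores A long score table (`pair_id`, `replica`, `metric`,
#'   `value`).
#' @param metric Metric name (must be registered).
#' @param replica Which replica to rank.
#' @param registry Metric registry (default built-ins).
#' @return A `ranking` tibble (`pair_id`, `value`, `rank`) with attributes
#'   `metric`, `direction`, `aggregation` and `missing_pairs` (pairs of the
#'   table that have no value here).
#' @export
rank_by_metric <- function(scores, metric, replica,
                           registry = metric_registry()) {
  validate_scores(scores)
  direction <- metric_direction(metric, registry)
  sub <- scores[scores$metric == metric & scores$replica == replica &
                  !is.na(scores$value), ]
  universe <- unique(scores$pair_id)
  missing_pairs <- setdiff(universe, sub$pair_id)
  new_ranking(rank_values(sub$pair_id, sub$value, direction),
              metric, direction, sprintf("replica_%s", replica),
              missing_pairs)
}

#' Rank pairs by a metric aggregated across replicas
#'
#' `mean` averages the available replica values per pair; `best` takes the
#' best available value (minimum for lower-is-better metrics, maximum for
#' higher-is-better ones). Ranking then proceeds as in
#' [rank_by_metric()].
#'
#' @inheritParams rank_by_metric
#' @param mode `"mean"` or `"best"`.
#' @return A `ranking` tibble.
#' @export
aggregate_replicas <- function(scores, metric, mode = c("mean", "best"),
                               registry = metric_registry()) {
  mode <- match.arg(mode)
  validate_scores(scores)
  direction <- metric_direction(metric, registry)
  sub <- scores[scores$metric == metric & !is.na(scores$value), ]
  universe <- unique(scores$pair_id)
  agg <- sub |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(value = if (mode == "mean") mean(.data$value)
                     else if (direction == "lower") min(.data$value)
                     else max(.data$value),
                     .groups = "drop")
  missing_pairs <- setdiff(universe, agg$pair_id)
  new_ranking(rank_values(agg$pair_id, agg$value, direction),
              metric, direction, mode, missing_pairs)
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking> %s (%s-is-better, %s): %d pairs ranked, %d missing\n",
              attr(x, "metric"), attr(x, "direction"), attr(x, "aggregation"),
              nrow(x), length(attr(x, "missing_pairs"))))
  NextMethod()
}

#' @export
tidy.ranking <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(metric = attr(x, "metric"),
                  aggregation = attr(x, "aggregation"))
}

#' @export
glance.ranking <- function(x, ...) {
  tibble::tibble(metric = attr(x, "metric"),
                 direction = attr(x, "direction"),
                 aggregation = attr(x, "aggregation"),
                 n_ranked = nrow(x),
                 n_missing = length(attr(x, "missing_pairs")))
}

#' Completeness report of a ranking
#'
#' Pairs that appear in the score table but carry no value under the
#' ranking's metric/aggregation (e.g. failed MD runs). They are excluded
#' from the ranking, never imputed.
#'
#' @param rk A `ranking`.
#' @return A tibble with column `pair_id`.
#' @export
completeness_report <- function(rk) {
  tibble::tibble(pair_id = attr(rk, "missing_pairs"))
}
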