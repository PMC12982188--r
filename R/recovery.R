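# Replica-aware recovery analytics: rank confidence intervals, score-at-rank
# confidence bands, recovery positions and violin summaries.
#
# Stochastic scoring stages (Monte-Carlo docking, quasiergodic MD rescoring)
# are run in R independent replicas; the replica spread is what turns a bare
# ranking into a ranking with uncertainty. With R as small as 4 the default
# interval is a Student-t interval over replicas; a min-max envelope is
# available as the conservative alternative.

ci_bounds <- function(values, ci = c("t", "range"), level = 0.95) {
  ci <- match.arg(ci)
  n <- length(values)
  m <- mean(values)
  if (n < 2L) return(c(lower = NA_real_, mean = m, upper = NA_real_))
  if (ci == "range") {
    return(c(lower = min(values), mean = m, upper = max(values)))
  }
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  c(lower = m - tq * se, mean = m, upper = m + tq * se)
}

#' Rank confidence intervals across replicas
#'
#' Ranks every replica separately with [rank_by_metric()], then summarises
#' each pair's ranks: point estimate = mean of per-replica ranks; 95%
#' interval = mean +/- t(0.975, n-1) * SE (or the min-max envelope), rounded
#' outward to integers and clipped to `[1, N']`. Pairs with fewer than two
#' replica values get an explicit `insufficient_replicas` note instead of an
#' interval.
#'
#' @param scores A long score table.
#' @param metric Metric name.
#' @param pairs Optional pair ids to restrict to (default: all ranked
#'   pairs).
#' @param registry Metric registry.
#' @param ci `"t"` (default) or `"range"`.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `pair_id`, `n_replicas`, `point`, `lower`, `upper`,
#'   `width`, `note`.
#' @export
rank_confidence <- function(scores, metric, pairs = NULL,
                            registry = metric_registry(),
                            ci = c("t", "range"), level = 0.95) {
  ci <- match.arg(ci)
  validate_scores(scores)
  reps <- sort(unique(scores$replica[scores$metric == metric &
                                       !is.na(scores$value)]))
  if (!length(reps)) {
    rlang::abort(sprintf("no values for metric '%s'", metric),
                 class = "decoybench_bad_input")
  }
  per_rep <- purrr::map(reps, function(r) {
    rk <- rank_by_metric(scores, metric, r, registry)
    stats::setNames(rk$rank, rk$pair_id)
  })
  n_prime <- max(vapply(per_rep, length, integer(1L)))
  all_pairs <- sort(unique(unlist(lapply(per_rep, names))))
  if (!is.null(pairs)) all_pairs <- intersect(all_pairs, pairs)
  rows <- purrr::map_dfr(all_pairs, function(p) {
    ranks <- unlist(lapply(per_rep, function(m) unname(m[p])))
    ranks <- ranks[!is.na(ranks)]
    n <- length(ranks)
    if (n < 2L) {
      return(tibble::tibble(pair_id = p, n_replicas = n,
                            point = mean(ranks), lower = NA_real_,
                            upper = NA_real_, width = NA_real_,
                            note = "insufficient_replicas"))
    }
    b <- ci_bounds(ranks, ci, level)
    lo <- max(1, floor(b[["lower"]]))
    hi <- min(n_prime, ceiling(b[["upper"]]))
    tibble::tibble(pair_id = p, n_replicas = n, point = b[["mean"]],
                   lower = lo, upper = hi, width = hi - lo, note = "")
  })
  rows
}

#' Score-at-rank confidence band with active placements (recovery curve)
#'
#' For every rank position r, collects the r-th best score from each
#' replica and forms mean and 95% band; the mean curve is monotone in the
#' metric's direction by construction. Replicas are aligned on the pairs
#' present in all of them; dropped pairs are reported. When labels are
#' available, each binder is placed both by the rank of its mean score
#' ("rank of means", how an averaged screen would order it) and by its mean
#' per-replica rank ("mean of ranks"); the two coincide for identical
#' replicas and may differ otherwise.
#'
#' @inheritParams rank_confidence
#' @param labels Optional labels data frame (`pair_id`, `label`); defaults
#'   to a `label` column of `scores` when present.
#' @return A `recovery_curve`: tibble (`rank`, `mean`, `lower`, `upper`,
#'   `is_active`) with attributes `actives` (per-binder placement tibble
#'   with rank CIs), `metric`, `direction`, `n_replicas`, `dropped_pairs`,
#'   `ci`.
#' @export
score_band <- function(scores, metric, labels = NULL,
                       registry = metric_registry(), ci = c("t", "range"),
                       level = 0.95) {
  ci <- match.arg(ci)
  validate_scores(scores)
  direction <- metric_direction(metric, registry)
  sub <- scores[scores$metric == metric & !is.na(scores$value), ]
  reps <- sort(unique(sub$replica))
  if (length(reps) < 2L) {
    rlang::abort("score_band needs at least 2 replicas",
                 class = "decoybench_bad_input")
  }
  by_rep <- split(sub, sub$replica)
  common <- Reduce(intersect, lapply(by_rep, function(d) d$pair_id))
  dropped <- setdiff(unique(sub$pair_id), common)
  n_prime <- length(common)
  if (n_prime < 1L) {
    rlang::abort("no pair has values in every replica",
                 class = "decoybench_bad_input")
  }
  sorted <- vapply(by_rep, function(d) {
    d <- d[d$pair_id %in% common, ]
    rank_values(d$pair_id, d$value, direction)$value
  }, numeric(n_prime))
  if (n_prime == 1L) sorted <- matrix(sorted, nrow = 1L)
  band <- t(apply(sorted, 1L, ci_bounds, ci = ci, level = level))
  curve <- tibble::tibble(rank = seq_len(n_prime),
                          mean = band[, "mean"],
                          lower = band[, "lower"],
                          upper = band[, "upper"],
                          is_active = FALSE)

  actives <- tibble::tibble(pair_id = character(), rank_of_means = integer(),
                            mean_of_ranks = numeric(), lower = numeric(),
                            upper = numeric())
  labels <- tryCatch(resolve_labels(scores, labels), error = function(e) NULL)
  if (!is.null(labels)) {
    binders <- intersect(labels$pair_id[labels$label == "binder"], common)
    if (length(binders)) {
      sub_common <- sub[sub$pair_id %in% common, ]
      mean_rk <- aggregate_replicas(sub_common, metric, "mean", registry)
      rom <- stats::setNames(mean_rk$rank, mean_rk$pair_id)
      rci <- rank_confidence(sub_common, metric, pairs = binders, registry,
                             ci = ci, level = level)
      actives <- tibble::tibble(
        pair_id = sort(binders),
        rank_of_means = as.integer(rom[sort(binders)])
      ) |>
        dplyr::left_join(rci, by = "pair_id") |>
        dplyr::rename(mean_of_ranks = "point") |>
        dplyr::select("pair_id", "rank_of_means", "mean_of_ranks", "lower",
                      "upper")
      curve$is_active[actives$rank_of_means] <- TRUE
    }
  }
  structure(curve,
            class = c("recovery_curve", "tbl_df", "tbl", "data.frame"),
            actives = actives, metric = metric, direction = direction,
            n_replicas = length(reps), dropped_pairs = dropped, ci = ci)
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %s over %d replicas: %d ranks, %d active marks, %d dropped pair(s)\n",
              attr(x, "metric"), attr(x, "n_replicas"), nrow(x),
              sum(x$is_active), length(attr(x, "dropped_pairs"))))
  NextMethod()
}

#' @export
tidy.recovery_curve <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.recovery_curve <- function(x, ...) {
  tibble::tibble(metric = attr(x, "metric"),
                 direction = attr(x, "direction"),
                 n_ranks = nrow(x),
                 n_replicas = attr(x, "n_replicas"),
                 n_active_marks = sum(x$is_active),
                 n_dropped = length(attr(x, "dropped_pairs")),
                 ci = attr(x, "ci"))
}

#' Active placements of a recovery curve
#'
#' @param x A `recovery_curve` from [score_band()].
#' @return The per-binder placement tibble (`rank_of_means`,
#'   `mean_of_ranks`, rank CI bounds).
#' @export
curve_actives <- function(x) attr(x, "actives")

#' Ranks of the active pairs in a ranking
#'
#' The marks of a recovery plot: where the binders sit in the ordered list.
#'
#' @param rk A `ranking`.
#' @param labels Labels data frame (`pair_id`, `label`).
#' @return A tibble (`pair_id`, `rank`) sorted by rank; zero rows when
#'   there are no labeled binders.
#' @export
recovery_positions <- function(rk, labels) {
  labels <- resolve_labels(tibble::as_tibble(rk), labels)
  binders <- labels$pair_id[labels$label == "binder"]
  out <- tibble::as_tibble(rk)[, c("pair_id", "rank")]
  out <- out[out$pair_id %in% binders, ]
  dplyr::arrange(out, .data$rank)
}

#' Violin summary of active ranks
#'
#' Summarises the ranks that a metric assigns to the active pairs across
#' replicas: median, linear-interpolation quartiles, min and max — the
#' numbers a violin/box rendering needs. Pooling `"per_active"` keeps one
#' distribution per binder (its ranks across replicas); `"pooled"` merges
#' all binders' replica ranks into one distribution per metric.
#'
#' @inheritParams rank_confidence
#' @param labels Labels data frame (`pair_id`, `label`); defaults to a
#'   `label` column of `scores`.
#' @param pooling `"pooled"` (default) or `"per_active"`.
#' @return A tibble with `metric`, (optionally `pair_id`,) `n`, `median`,
#'   `q1`, `q3`, `min`, `max`.
#' @export
rank_distribution_summary <- function(scores, metric, labels = NULL,
                                      registry = metric_registry(),
                                      pooling = c("pooled", "per_active")) {
  pooling <- match.arg(pooling)
  validate_scores(scores)
  labels <- resolve_labels(scores, labels)
  binders <- labels$pair_id[labels$label == "binder"]
  reps <- sort(unique(scores$replica[scores$metric == metric &
                                       !is.na(scores$value)]))
  rk_long <- purrr::map_dfr(reps, function(r) {
    rk <- rank_by_metric(scores, metric, r, registry)
    tibble::as_tibble(rk) |>
      dplyr::filter(.data$pair_id %in% binders) |>
      dplyr::mutate(replica = r)
  })
  if (!nrow(rk_long)) {
    rlang::abort("no active ranks available for this metric",
                 class = "decoybench_bad_input")
  }
  summarise_ranks <- function(d) {
    q <- stats::quantile(d$rank, c(0.25, 0.5, 0.75), type = 7L, names = FALSE)
    tibble::tibble(n = nrow(d), median = q[2L], q1 = q[1L], q3 = q[3L],
                   min = min(d$rank), max = max(d$rank))
  }
  if (pooling == "pooled") {
    dplyr::bind_cols(tibble::tibble(metric = metric),
                     summarise_ranks(rk_long))
  } else {
    rk_long |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::group_modify(~ summarise_ranks(.x)) |>
      dplyr::ungroup() |>
      dplyr::mutate(metric = metric) |>
      dplyr::select("metric", dplyr::everything())
  }
}
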