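# Enrichment factors over ranked benchmark lists.

#' Enrichment factor at a top fraction of a ranking
#'
#' `EF(x) = (actives in top n_top / n_top) / (A / N')` with
#' `n_top = ceiling(x * N')` — the ceiling convention, so the top 10% of a
#' 78-compound list is 8 compounds. EF is 1 in expectation for a random
#' ranking, 0 when no active makes the cut, and reaches
#' `(min(n_top, A) / n_top) / (A / N')` for perfect separation.
#'
#' @param rk A `ranking`.
#' @param labels Labels data frame (`pair_id`, `label`).
#' @param top_frac Top fraction x, `0 < x <= 1` (default 0.10).
#' @return A one-row tibble: `metric`, `aggregation`, `top_frac`, `n_top`,
#'   `n_ranked`, `n_actives`, `n_actives_top`, `ef`, `ef_max`, `note`.
#'   With zero labeled actives `ef` is `NA` and the note says so (an
#'   explicit undefined-EF result, not an error).
#' @export
enrichment_factor <- function(rk, labels, top_frac = 0.10) {
  stopifnot(top_frac > 0, top_frac <= 1)
  labels <- resolve_labels(tibble::as_tibble(rk), labels)
  n_prime <- nrow(rk)
  n_top <- as.integer(ceiling(top_frac * n_prime))
  pos <- recovery_positions(rk, labels)
  a_total <- nrow(pos)
  a_top <- sum(pos$rank <= n_top)
  if (a_total == 0L) {
    ef <- NA_real_
    ef_max <- NA_real_
    note <- "no labeled actives: EF undefined"
  } else {
    ef <- (a_top / n_top) / (a_total / n_prime)
    ef_max <- (min(n_top, a_total) / n_top) / (a_total / n_prime)
    note <- ""
  }
  tibble::tibble(metric = attr(rk, "metric"),
                 aggregation = attr(rk, "aggregation"),
                 top_frac = top_frac, n_top = n_top, n_ranked = n_prime,
                 n_actives = a_total, n_actives_top = a_top,
                 ef = ef, ef_max = ef_max, note = note)
}

#' Enrichment factors at several dilution-style cutoffs
#'
#' Convenience wrapper evaluating [enrichment_factor()] at a vector of top
#' fractions (e.g. the 1% and 10% cuts used when arguing about screening
#' deck dilutions).
#'
#' @inheritParams enrichment_factor
#' @param top_fracs Numeric vector of top fractions.
#' @return A tibble with one row per cutoff.
#' @export
enrichment_profile <- function(rk, labels, top_fracs = c(0.01, 0.05, 0.10,
                                                         0.25)) {
  purrr::map_dfr(top_fracs, function(x) enrichment_factor(rk, labels, x))
}
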