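# Seeded decoy sampling from filtered isomer pools, and the active-vs-decoy
# property comparison report.

#' Sample constitutional-isomer decoys for a set of actives
#'
#' For every active, draws `n_per_active` decoys uniformly at random without
#' replacement from the filtered isomer pool of that active's molecular
#' formula, excluding any structure isomorphic to one of the actives. When a
#' pool is smaller than requested, every pool member is taken and a shortfall
#' is recorded. Identical seed and inputs give identical output.
#'
#' @param actives A list of [molecule()]s (or a single molecule).
#' @param n_per_active Decoys per active (default 25).
#' @param pool Optional pre-built decoy pool (list of molecules, e.g. a
#'   filtered `isomer_set`); members are matched to actives by formula. When
#'   `NULL`, each active's pool is enumerated and filtered here.
#' @param seed Integer seed governing the sampling.
#' @param rules [sanity_rules()] used when enumerating pools internally.
#' @param max_isomers Enumeration cap per formula used when building pools
#'   internally (default 10000).
#' @return A `decoy_set`: actives, the per-active decoy lists, the seed, the
#'   requested count and a `shortfall` tibble (one row per active whose pool
#'   was exhausted).
#' @examples
#' ds <- sample_decoys(mol_from_smiles("CCCCCC", id = "hexane"),
#'                     n_per_active = 3, seed = 1)
#' tidy(ds)
#' @export
sample_decoys <- function(actives, n_per_active = 25L, pool = NULL,
                          seed = 1L, rules = sanity_rules(),
                          max_isomers = 10000L) {
  if (inherits(actives, "molecule")) actives <- list(actives)
  stopifnot(length(actives) >= 1L, n_per_active >= 1L)
  active_ids <- vapply(actives, function(m) m$id, character(1L))
  if (anyDuplicated(active_ids)) {
    rlang::abort("active molecules must have distinct ids",
                 class = "decoybench_bad_input")
  }
  active_formulas <- vapply(actives, mol_formula, character(1L))
  active_keys <- vapply(actives, mol_canonical, character(1L))

  pool_for <- function(formula) {
    if (!is.null(pool)) {
      pool[vapply(pool, mol_formula, character(1L)) == formula]
    } else {
      iso <- enumerate_isomers(formula, max_isomers = max_isomers)
      apply_sanity_filters(iso, rules)$molecules
    }
  }

  decoys <- vector("list", length(actives))
  names(decoys) <- active_ids
  shortfall <- tibble::tibble(active_id = character(), pool_size = integer(),
                              requested = integer())
  with_seed(seed, {
    for (a in seq_along(actives)) {
      pl <- pool_for(active_formulas[a])
      keys <- vapply(pl, mol_canonical, character(1L))
      pl <- pl[!keys %in% active_keys]
      take <- min(length(pl), n_per_active)
      if (take < n_per_active) {
        shortfall <- dplyr::bind_rows(shortfall, tibble::tibble(
          active_id = active_ids[a], pool_size = length(pl),
          requested = as.integer(n_per_active)
        ))
      }
      picked <- pl[sort(sample.int(length(pl), take))]
      for (d in seq_along(picked)) {
        picked[[d]]$id <- sprintf("%s_decoy%03d", active_ids[a], d)
      }
      decoys[[a]] <- picked
    }
  })
  if (nrow(shortfall)) {
    rlang::warn(sprintf(
      "decoy pool exhausted for %d active(s); see the shortfall table",
      nrow(shortfall)
    ), class = "decoybench_shortfall")
  }
  structure(list(actives = actives, decoys = decoys, seed = as.integer(seed),
                 n_per_active = as.integer(n_per_active),
                 shortfall = shortfall),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("<decoy_set> %d active(s), %d decoys (%d requested per active, seed %d)\n",
              length(x$actives), sum(lengths(x$decoys)), x$n_per_active,
              x$seed))
  invisible(x)
}

#' All molecules of a decoy set as one list
#'
#' @param x A `decoy_set`.
#' @return A named list: actives first, then decoys.
#' @export
decoy_set_molecules <- function(x) {
  out <- c(x$actives, unlist(x$decoys, recursive = FALSE))
  names(out) <- vapply(out, function(m) m$id, character(1L))
  out
}

#' @export
tidy.decoy_set <- function(x, ...) {
  rows <- list()
  for (a in seq_along(x$actives)) {
    act <- x$actives[[a]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      active_id = act$id, id = act$id, role = "active",
      formula = mol_formula(act)
    )
    for (d in x$decoys[[a]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        active_id = act$id, id = d$id, role = "decoy",
        formula = mol_formula(d)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.decoy_set <- function(x, ...) {
  n_act <- length(x$actives)
  n_dec <- sum(lengths(x$decoys))
  tibble::tibble(
    n_actives = n_act, n_decoys = n_dec, n_total = n_act + n_dec,
    n_per_active = x$n_per_active, seed = x$seed,
    ratio = ratio_string(n_act, n_dec),
    shortfall = nrow(x$shortfall) > 0L
  )
}

#' Active-vs-decoy property comparison
#'
#' Summarises each numeric descriptor of [compute_properties()] for the
#' active and decoy sets side by side: mean, median, min, max for each
#' group, plus the absolute difference of group means. Constitutional
#' isomers of an active share its formula, so the weight difference for
#' pure isomer decoys is exactly zero; disjoint-formula decoys simply show a
#' nonzero difference — the report describes, it does not judge.
#'
#' @param actives,decoys Lists of [molecule()]s, or a `decoy_set` as
#'   `actives` (in which case `decoys` is ignored).
#' @param amide_rules Passed to [compute_properties()].
#' @return A tibble with one row per property.
#' @export
property_match_report <- function(actives, decoys = NULL, amide_rules = FALSE) {
  if (inherits(actives, "decoy_set")) {
    ds <- actives
    actives <- ds$actives
    decoys <- unlist(ds$decoys, recursive = FALSE)
  }
  if (inherits(actives, "molecule")) actives <- list(actives)
  if (inherits(decoys, "molecule")) decoys <- list(decoys)
  stopifnot(length(actives) >= 1L, length(decoys) >= 1L)
  pa <- compute_properties(actives, amide_rules = amide_rules)
  pd <- compute_properties(decoys, amide_rules = amide_rules)
  props <- c("mw", "hbd", "hba", "rotors", "charge", "rings")
  long <- function(df, set) {
    df |>
      dplyr::select(dplyr::all_of(props)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "property") |>
      dplyr::group_by(.data$property) |>
      dplyr::summarise(mean = mean(.data$value), median = stats::median(.data$value),
                       min = min(.data$value), max = max(.data$value),
                       .groups = "drop") |>
      dplyr::mutate(set = set)
  }
  wide <- dplyr::bind_rows(long(pa, "actives"), long(pd, "decoys")) |>
    tidyr::pivot_wider(names_from = "set",
                       values_from = c("mean", "median", "min", "max"),
                       names_glue = "{set}_{.value}") |>
    dplyr::mutate(abs_mean_diff = abs(.data$actives_mean - .data$decoys_mean))
  wide[match(props, wide$property), ]
}

ratio_string <- function(n_actives, n_decoys) {
  if (n_actives == 0L) return(NA_character_)
  sprintf("1:%d", as.integer(round(n_decoys / n_actives)))
}
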