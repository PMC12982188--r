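# Synthetic fixture generators.
#
# These stand in for the outputs of external docking/MD stages so the whole
# analytics stack can be exercised and tested without any external tool:
# (a) score tables with a planted active-vs-decoy separation and independent
# per-replica noise, and (b) complex collections with controlled
# protein-identity degeneracy. All synthetic — the generators emulate the
# shape and statistics of real pipeline output, not any particular system.

#' Configuration for synthetic score table generation
#'
#' The default configuration mirrors a small isomer-decoy benchmark: 3
#' actives against 75 decoys scored in 4 independent replicas of a
#' predicted-affinity metric in kcal/mol, decoy scores centred at
#' -6 kcal/mol (spread 1 kcal/mol), actives shifted 2 kcal/mol toward the
#' better end, and 0.3 kcal/mol of independent per-replica noise.
#'
#' @param n_actives Number of active pairs (>= 0).
#' @param n_decoys Number of decoy pairs (>= 1).
#' @param replicas Number of replicas (>= 1).
#' @param metric Metric name (must be in `registry`).
#' @param shift Planted separation delta: how far active base scores move
#'   toward the metric's better direction, in metric units.
#' @param noise Per-replica noise sd sigma (>= 0), in metric units.
#' @param base_mean,base_sd Decoy base score distribution (normal).
#' @param seed Integer seed.
#' @param registry Metric registry used to resolve the direction.
#' @return A `synthetic_score_config` list.
#' @export
synthetic_score_config <- function(n_actives = 3L, n_decoys = 75L,
                                   replicas = 4L, metric = "gnina_affinity",
                                   shift = 2, noise = 0.3,
                                   base_mean = -6, base_sd = 1,
                                   seed = 1L,
                                   registry = metric_registry()) {
  stopifnot(n_actives >= 0L, n_decoys >= 1L, replicas >= 1L, noise >= 0,
            base_sd >= 0)
  direction <- metric_direction(metric, registry)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 replicas = as.integer(replicas), metric = metric,
                 direction = direction, shift = shift, noise = noise,
                 base_mean = base_mean, base_sd = base_sd,
                 seed = as.integer(seed)),
            class = "synthetic_score_config")
}

#' Generate a synthetic long-format score table
#'
#' Each pair gets a latent base score (decoys from the base distribution,
#' actives shifted by `shift` toward the better end of the metric); each
#' replica observes the base score plus independent Gaussian noise.
#' Identical configuration (including seed) gives an identical table.
#'
#' @param config A [synthetic_score_config()].
#' @return A tibble (`pair_id`, `replica`, `metric`, `value`, `label`)
#'   suitable for every ranking/recovery function.
#' @examples
#' scores <- generate_synthetic_scores(synthetic_score_config(seed = 7))
#' dplyr::count(scores, label)
#' @export
generate_synthetic_scores <- function(config = synthetic_score_config()) {
  stopifnot(inherits(config, "synthetic_score_config"))
  sgn <- if (config$direction == "lower") -1 else 1
  A <- config$n_actives
  D <- config$n_decoys
  ids <- c(if (A > 0L) sprintf("ACT%03d", seq_len(A)),
           sprintf("DEC%03d", seq_len(D)))
  label <- c(rep("binder", A), rep("decoy", D))
  with_seed(config$seed, {
    base <- stats::rnorm(A + D, config$base_mean, config$base_sd)
    base[seq_len(A)] <- base[seq_len(A)] + sgn * config$shift
    tidyr::expand_grid(pair_id = ids, replica = seq_len(config$replicas)) |>
      dplyr::mutate(
        metric = config$metric,
        value = base[match(.data$pair_id, ids)] +
          stats::rnorm(dplyr::n(), 0, config$noise),
        label = label[match(.data$pair_id, ids)]
      )
  })
}

#' Generate a synthetic complex collection with identity degeneracy
#'
#' Builds `n` protein-ligand complex records whose protein identities are
#' shared within groups of the given sizes — the degeneracy pattern that
#' makes "random" ligand-protein pairings turn into true binders. Cognate
#' ligands are unique per structure; a synthetic dissociation-constant
#' annotation is attached as provenance.
#'
#' @param n Number of structures.
#' @param group_sizes Integer vector of identity group sizes, summing to
#'   `n` (default all 1: no degeneracy).
#' @param seed Integer seed (affinity annotations only).
#' @return A collection tibble (`complex_id`, `uniprot_id`, `ligand_id`,
#'   `affinity_type`, `affinity_value`).
#' @examples
#' generate_synthetic_collection(5, group_sizes = c(2, 1, 1, 1), seed = 1)
#' @export
generate_synthetic_collection <- function(n, group_sizes = rep(1L, n),
                                          seed = 1L) {
  n <- as.integer(n)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L) || sum(group_sizes) != n) {
    rlang::abort(sprintf(
      "group_sizes must be positive and sum to n (%d); got sum %d",
      n, sum(group_sizes)), class = "decoybench_bad_input")
  }
  identity <- rep(sprintf("SYNP%04d", seq_along(group_sizes)), group_sizes)
  with_seed(seed, tibble::tibble(
    complex_id = sprintf("CPX%04d", seq_len(n)),
    uniprot_id = identity,
    ligand_id = sprintf("LIG%04d", seq_len(n)),
    affinity_type = "K_D",
    affinity_value = signif(10^stats::runif(n, -9, -5), 3)
  ))
}

#' Degeneracy group sizes that plant a chosen number of cross binders
#'
#' With forced same-identity inclusion ([build_randomized_pairs()] with
#' `force_same_identity = TRUE`), a collection whose identity groups have
#' sizes g contributes `sum(g * (g - 1))` cross-structure binding pairs.
#' This helper greedily assembles group sizes for a requested count, filling
#' up with singletons.
#'
#' @param n Number of structures.
#' @param n_cross_binders Desired number of cross-structure binder pairs.
#' @return An integer vector of group sizes summing to `n`.
#' @examples
#' g <- degeneracy_groups(29, 26)
#' sum(g * (g - 1))  # 26
#' @export
degeneracy_groups <- function(n, n_cross_binders) {
  target <- as.integer(n_cross_binders)
  sizes <- integer(0)
  left <- as.integer(n)
  while (target > 0L) {
    g <- 2L
    while (g * (g - 1L) <= target && (g + 1L) * g <= target &&
           g + 1L <= left) {
      g <- g + 1L
    }
    if (g > left || g * (g - 1L) > target) {
      rlang::abort(sprintf(
        "cannot realise %d cross binders with %d structures",
        n_cross_binders, n), class = "decoybench_bad_input")
    }
    sizes <- c(sizes, g)
    target <- target - g * (g - 1L)
    left <- left - g
  }
  c(sizes, rep(1L, left))
}
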