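# Metric directionality registry.
#
# Every scoring metric must declare which direction is "better" before any
# ranking is computed. The built-ins cover the usual outputs of a
# docking + MD + end-state rescoring pipeline; user metrics (per-term energy
# breakdowns and the like) are registered on top.

#' Built-in metric registry
#'
#' Directions: predicted affinity in kcal/mol (more negative is better),
#' CNN pose score (a probability, higher is better), CNN affinity in pK
#' units (higher is better), MM-GBSA / MM-PBSA binding enthalpies in
#' kcal/mol (lower is better), and ligand heavy-atom RMSD in Angstrom
#' (lower is better).
#'
#' @return A tibble with columns `metric`, `direction`
#'   (`"lower"`/`"higher"`), `units`.
#' @export
metric_registry <- function() {
  tibble::tribble(
    ~metric,          ~direction, ~units,
    "gnina_affinity", "lower",    "kcal/mol",
    "cnn_pose_score", "higher",   "probability",
    "cnn_affinity",   "higher",   "pK",
    "mm_gbsa",        "lower",    "kcal/mol",
    "mm_pbsa",        "lower",    "kcal/mol",
    "rmsd",           "lower",    "angstrom"
  )
}

#' Register an additional metric
#'
#' @param registry A registry tibble (default the built-ins).
#' @param metric Metric name.
#' @param direction `"lower"` or `"higher"` (which end is better).
#' @param units Unit string (free text).
#' @return The extended registry.
#' @examples
#' register_metric(metric_registry(), "egb", "lower", "kcal/mol")
#' @export
register_metric <- function(registry = metric_registry(), metric, direction,
                            units = "") {
  direction <- match.arg(direction, c("lower", "higher"))
  if (metric %in% registry$metric) {
    rlang::abort(sprintf("metric '%s' is already registered", metric),
                 class = "decoybench_bad_metric")
  }
  dplyr::bind_rows(registry,
                   tibble::tibble(metric = metric, direction = direction,
                                  units = units))
}

metric_direction <- function(metric, registry) {
  hit <- registry$direction[registry$metric == metric]
  if (!length(hit)) {
    rlang::abort(sprintf(
      "metric '%s' is not registered; declare its direction with register_metric()",
      metric), class = "decoybench_bad_metric")
  }
  hit[[1L]]
}

validate_scores <- function(scores) {
  need <- c("pair_id", "replica", "metric", "value")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    rlang::abort(paste0("score table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "decoybench_bad_input")
  }
  key <- paste(scores$pair_id, scores$replica, scores$metric)
  if (anyDuplicated(key)) {
    rlang::abort("(pair_id, replica, metric) must be unique in a score table",
                 class = "decoybench_bad_input")
  }
  invisible(scores)
}

# labels: explicit tibble wins; otherwise a label column embedded in the
# score table
resolve_labels <- function(scores, labels = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(scores)) {
      rlang::abort("no labels: supply a labels data frame (pair_id, label) or a label column",
                   class = "decoybench_bad_input")
    }
    labels <- dplyr::distinct(scores[, c("pair_id", "label")])
  }
  stopifnot(all(c("pair_id", "label") %in% names(labels)))
  labels <- dplyr::distinct(tibble::as_tibble(labels[, c("pair_id", "label")]))
  if (anyDuplicated(labels$pair_id)) {
    rlang::abort("conflicting labels for one pair_id",
                 class = "decoybench_bad_input")
  }
  bad <- setdiff(unique(labels$label), c("binder", "decoy"))
  if (length(bad)) {
    rlang::abort("labels must be 'binder' or 'decoy'",
                 class = "decoybench_bad_input")
  }
  labels
}

#' Read a long-format score table from CSV
#'
#' Columns: `pair_id`, `replica`, `metric`, `value` (and optionally
#' `label`).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_scores <- function(path) {
  validate_scores(read_bench_csv(path))
}
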