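# Randomized ligand-protein benchmark construction.
#
# Every structure of a complex collection receives its own ligand back
# (redocking, a guaranteed binder) plus k noncognate ligands drawn at random
# (crossdocking, presumed decoys). Collections of experimental structures
# are frequently degenerate — several entries share one protein accession —
# so a "random" pairing can silently be a true binder; relabeling by protein
# identity recovers those pairs.

validate_collection <- function(collection) {
  need <- c("complex_id", "uniprot_id", "ligand_id")
  missing <- setdiff(need, names(collection))
  if (length(missing)) {
    rlang::abort(paste0("collection lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "decoybench_bad_input")
  }
  if (anyDuplicated(collection$complex_id)) {
    rlang::abort("complex_id must be unique within a collection",
                 class = "decoybench_bad_input")
  }
  if (any(is.na(collection$uniprot_id) | !nzchar(collection$uniprot_id))) {
    rlang::abort("every complex needs a nonempty protein identity",
                 class = "decoybench_bad_input")
  }
  invisible(collection)
}

#' Build randomized protein-ligand benchmark pairs
#'
#' For each structure in the collection, emits one redocking pair (its own
#' cognate ligand) and `decoys_per_structure` crossdocking pairs whose
#' ligands are sampled uniformly without replacement from the other
#' structures' cognate ligands. Labels start as the naive assignment
#' (redock = binder, crossdock = decoy); run [relabel_by_identity()]
#' afterwards to recover accidental binders among the crossdocks.
#'
#' @param collection A data frame with columns `complex_id`, `uniprot_id`,
#'   `ligand_id` (extra columns such as affinity annotations are carried as
#'   provenance and ignored here).
#' @param decoys_per_structure Number of noncognate ligands per structure
#'   (`k`); must be smaller than the collection size.
#' @param seed Integer seed for the ligand sampling.
#' @param force_same_identity When TRUE, ligands whose source structure
#'   shares the protein identity of the receiving structure are always
#'   included among its `k` crossdock ligands (the remaining slots are
#'   sampled). This plants an exactly known number of cross-structure
#'   binders and is what the synthetic paper-shaped fixtures use; with the
#'   default FALSE the draw is fully uniform.
#' @return A tibble of benchmark pairs: `pair_id`, `complex_id`,
#'   `ligand_id`, `mode` (`"redock"`/`"crossdock"`), `label`
#'   (`"binder"`/`"decoy"`), `provenance`.
#' @examples
#' coll <- generate_synthetic_collection(5, seed = 1)
#' build_randomized_pairs(coll, decoys_per_structure = 2, seed = 1)
#' @export
build_randomized_pairs <- function(collection, decoys_per_structure,
                                   seed = 1L, force_same_identity = FALSE) {
  validate_collection(collection)
  n <- nrow(collection)
  k <- as.integer(decoys_per_structure)
  if (k < 0L) rlang::abort("decoys_per_structure must be >= 0",
                           class = "decoybench_bad_input")
  if (k >= n) {
    rlang::abort(sprintf(
      "decoys_per_structure (%d) must be smaller than the collection size (%d): each structure can only receive ligands from the other structures",
      k, n), class = "decoybench_bad_input")
  }
  prov <- sprintf("randomized k=%d seed=%d", k, seed)
  rows <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      own <- collection$ligand_id[i]
      others <- setdiff(seq_len(n), i)
      chosen <- integer(0)
      if (k > 0L) {
        if (force_same_identity) {
          same <- others[collection$uniprot_id[others] ==
                           collection$uniprot_id[i]]
          if (length(same) > k) {
            rlang::abort(sprintf(
              "structure %s shares its identity with %d others but only %d crossdock slots exist",
              collection$complex_id[i], length(same), k),
              class = "decoybench_bad_input")
          }
          rest <- setdiff(others, same)
          chosen <- c(same, rest[sample.int(length(rest), k - length(same))])
        } else {
          chosen <- others[sample.int(length(others), k)]
        }
        chosen <- sort(chosen)
      }
      lig <- c(own, collection$ligand_id[chosen])
      rows[[i]] <- tibble::tibble(
        complex_id = collection$complex_id[i],
        ligand_id = lig,
        mode = c("redock", rep("crossdock", length(chosen)))
      )
    }
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      pair_id = paste(.data$complex_id, .data$ligand_id, sep = ":"),
      label = dplyr::if_else(.data$mode == "redock", "binder", "decoy"),
      provenance = prov
    ) |>
    dplyr::select("pair_id", "complex_id", "ligand_id", "mode", "label",
                  "provenance")
}

#' Relabel benchmark pairs using protein-identity degeneracy
#'
#' A pair is a binder exactly when its (ligand, protein identity) is in the
#' known-binder relation. The default relation is the cognate relation
#' expanded over identity duplicates: every ligand binds the protein
#' identity of its source structure, hence also any other structure of the
#' same identity. Additional experimentally known binders can be supplied.
#' Relabeling only changes labels, never membership, and is idempotent.
#'
#' @param pairs A pair tibble from [build_randomized_pairs()].
#' @param collection The complex collection the pairs were built from.
#' @param known_binders Optional extra relation rows: a data frame with
#'   columns `ligand_id`, `uniprot_id`.
#' @return The pair tibble with refreshed `label`.
#' @export
relabel_by_identity <- function(pairs, collection, known_binders = NULL) {
  validate_collection(collection)
  unknown <- setdiff(unique(pairs$complex_id), collection$complex_id)
  if (length(unknown)) {
    rlang::abort(paste0("pairs reference complex id(s) missing from the collection: ",
                        paste(unknown, collapse = ", ")),
                 class = "decoybench_bad_input")
  }
  relation <- tibble::tibble(
    ligand_id = collection$ligand_id,
    uniprot_id = collection$uniprot_id
  )
  if (!is.null(known_binders)) {
    stopifnot(all(c("ligand_id", "uniprot_id") %in% names(known_binders)))
    relation <- dplyr::bind_rows(
      relation,
      tibble::as_tibble(known_binders[, c("ligand_id", "uniprot_id")])
    )
  }
  relation <- dplyr::distinct(relation)
  idmap <- stats::setNames(collection$uniprot_id, collection$complex_id)
  pairs |>
    dplyr::mutate(
      .target_identity = idmap[.data$complex_id],
      label = dplyr::if_else(
        paste(.data$ligand_id, .data$.target_identity) %in%
          paste(relation$ligand_id, relation$uniprot_id),
        "binder", "decoy"
      )
    ) |>
    dplyr::select(-".target_identity")
}

#' Summarise a benchmark pair set
#'
#' @param pairs A benchmark pair tibble.
#' @return A one-row tibble: totals by mode and label plus the decoy:active
#'   ratio reported as `"1:r"` with `r` rounded to the nearest integer.
#' @export
summarize_set <- function(pairs) {
  stopifnot(nrow(pairs) >= 1L)
  n_binder <- sum(pairs$label == "binder")
  n_decoy <- sum(pairs$label == "decoy")
  tibble::tibble(
    n_pairs = nrow(pairs),
    n_redock = sum(pairs$mode == "redock"),
    n_crossdock = sum(pairs$mode == "crossdock"),
    n_binder = n_binder,
    n_decoy = n_decoy,
    ratio = ratio_string(n_binder, n_decoy)
  )
}

#' Read a complex collection from CSV
#'
#' Expected columns: `complex_id`, `uniprot_id`, `ligand_id` and optionally
#' `affinity_type`, `affinity_value` (carried as provenance only).
#'
#' @param path CSV path.
#' @return A validated collection tibble.
#' @export
read_collection <- function(path) {
  validate_collection(read_bench_csv(path))
}

#' Write benchmark pairs to CSV
#'
#' @param pairs A benchmark pair tibble.
#' @param path Output path.
#' @param meta Named list of extra provenance values for the header.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, meta = list()) {
  write_stamped_csv(pairs, path, meta)
}

#' Per-pair job manifest for an external docking stage
#'
#' The package never runs docking; this emits one job line per pair naming
#' the receiving structure, the ligand to place, and the structure's
#' cognate ligand as the binding-site reference.
#'
#' @param pairs A benchmark pair tibble.
#' @param collection The complex collection (supplies the cognate reference
#'   ligand per structure).
#' @return A character vector of job lines.
#' @export
docking_manifest <- function(pairs, collection) {
  validate_collection(collection)
  ref <- stats::setNames(collection$ligand_id, collection$complex_id)
  sprintf("dock pair=%s receptor=%s ligand=%s reference_ligand=%s",
          pairs$pair_id, pairs$complex_id, pairs$ligand_id,
          ref[pairs$complex_id])
}
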