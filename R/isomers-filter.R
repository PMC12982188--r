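# Chemical sanity filters for enumerated isomers.
#
# Raw formula enumeration admits structures that are valence-legal but
# chemically unreasonable; the most prominent offenders are cumulated double
# bonds (an atom carrying two double bonds) inside small rings. The filter
# rules are explicit, named, and first-match-wins so every rejection is
# attributable to exactly one rule.

#' Sanity-filter rule configuration
#'
#' @param cumulene_in_ring Reject molecules with an atom bearing two double
#'   bonds that sits in a ring of size `max_ring_size` or smaller (default
#'   TRUE; rule name `"cumulene_in_ring"`).
#' @param cumulene_any Reject any cumulated double bonds, rings or not
#'   (default FALSE; rule `"cumulene_any"`). Linear allenes pass when off.
#' @param triple_in_ring Reject triple bonds inside rings of size
#'   `max_ring_size` or smaller (default FALSE; rule `"triple_in_ring"`).
#' @param max_ring_size Ring size threshold for the ring-scoped rules
#'   (default 8; large-ring cumulenes/alkynes are geometrically plausible).
#' @return A named list of class `sanity_rules`.
#' @export
sanity_rules <- function(cumulene_in_ring = TRUE, cumulene_any = FALSE,
                         triple_in_ring = FALSE, max_ring_size = 8L) {
  structure(list(cumulene_in_ring = isTRUE(cumulene_in_ring),
                 cumulene_any = isTRUE(cumulene_any),
                 triple_in_ring = isTRUE(triple_in_ring),
                 max_ring_size = as.integer(max_ring_size)),
            class = "sanity_rules")
}

.known_rules <- c("cumulene_in_ring", "cumulene_any", "triple_in_ring")

#' Apply chemical sanity filters to molecules
#'
#' Applies the enabled rules of a [sanity_rules()] configuration in the
#' fixed order `cumulene_in_ring`, `cumulene_any`, `triple_in_ring`; the
#' first matching rule claims the rejection. Filtering is idempotent.
#'
#' @param mols A list of [molecule()]s (e.g. an `isomer_set`).
#' @param rules A [sanity_rules()] configuration, or a character vector of
#'   rule names to enable.
#' @return A list with elements `molecules` (the kept list) and `report`
#'   (a `filter_report`: input/kept counts and a rejection tibble with one
#'   `(id, rule)` row per rejected molecule).
#' @examples
#' benzene <- mol_from_smiles("C1=CC=CC=C1")
#' apply_sanity_filters(list(benzene))$report
#' @export
apply_sanity_filters <- function(mols, rules = sanity_rules()) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (is.character(rules)) {
    unknown <- setdiff(rules, .known_rules)
    if (length(unknown)) {
      rlang::abort(paste0("unknown filter rule(s): ",
                          paste(unknown, collapse = ", ")),
                   class = "decoybench_bad_rule")
    }
    rules <- sanity_rules(
      cumulene_in_ring = "cumulene_in_ring" %in% rules,
      cumulene_any = "cumulene_any" %in% rules,
      triple_in_ring = "triple_in_ring" %in% rules
    )
  }
  stopifnot(inherits(rules, "sanity_rules"))
  verdict <- vapply(mols, first_matching_rule, character(1L), rules = rules)
  kept <- mols[verdict == ""]
  rejected <- tibble::tibble(
    id = vapply(mols[verdict != ""], function(m) m$id, character(1L)),
    rule = verdict[verdict != ""]
  )
  report <- structure(
    list(n_input = length(mols), n_kept = length(kept), rejections = rejected),
    class = "filter_report"
  )
  attrs <- attributes(mols)
  out <- kept
  if (inherits(mols, "isomer_set")) {
    attributes(out) <- c(attributes(out),
                         attrs[c("formula", "feasible", "truncated")])
    class(out) <- "isomer_set"
  }
  list(molecules = out, report = report)
}

# name of the first matching enabled rule, or "" when the molecule passes
first_matching_rule <- function(m, rules) {
  b <- m$bonds
  dbl_count <- integer(length(m$element))
  if (nrow(b)) {
    dd <- b[b$order == 2L, , drop = FALSE]
    dbl_count <- tabulate(c(dd$from, dd$to), nbins = length(m$element))
  }
  cumulated <- which(dbl_count >= 2L)
  if (rules$cumulene_in_ring && length(cumulated)) {
    ring_size <- smallest_ring_per_atom(m)
    if (any(ring_size[cumulated] <= rules$max_ring_size)) {
      return("cumulene_in_ring")
    }
  }
  if (rules$cumulene_any && length(cumulated)) return("cumulene_any")
  if (rules$triple_in_ring && nrow(b) && any(b$order == 3L)) {
    ring_size <- smallest_ring_per_bond(m)
    if (any(b$order == 3L & ring_size <= rules$max_ring_size)) {
      return("triple_in_ring")
    }
  }
  ""
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in, %d kept, %d rejected\n",
              x$n_input, x$n_kept, nrow(x$rejections)))
  if (nrow(x$rejections)) print(dplyr::count(x$rejections, .data$rule))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$rejections

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_kept = x$n_kept,
                 n_rejected = nrow(x$rejections))
}
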