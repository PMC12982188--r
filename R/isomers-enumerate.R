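# Constitutional isomer enumeration.
#
# The enumerator performs an orderly depth-first generation over heavy-atom
# bond-order matrices: atoms are grouped into element classes, bond orders are
# assigned pair by pair in a fixed row-major order under valence and
# bond-budget pruning, a connected-growth rule restricts relabelings within
# element classes, and isomorphism rejection is done with canonical forms
# (BLISS canonical labeling of the order-coloured graph). Hydrogens are
# implicit: every atom's free valence after bonding becomes hydrogen, so the
# hydrogen total of the formula fixes the total bond order
#   B = (sum of valences - H) / 2
# exactly, which is what makes exhaustive generation tractable.

#' Enumeration constraints for constitutional isomer generation
#'
#' @param formula Molecular formula (string like `"C4H10"` or named counts).
#' @param max_isomers Emission cap; generation stops once this many distinct
#'   isomers have been found and the result is flagged truncated. Default
#'   unlimited.
#' @param max_rings Maximum number of independent rings. Default unlimited.
#' @param allow_triple Permit triple bonds (default TRUE).
#' @param s_valence Valence used for sulfur: 2 (default), 4 or 6.
#' @param p_valence Valence used for phosphorus: 3 (default) or 5.
#' @return A list of settings of class `enumeration_constraints`.
#' @export
enumeration_constraints <- function(formula, max_isomers = Inf,
                                    max_rings = Inf, allow_triple = TRUE,
                                    s_valence = 2L, p_valence = 3L) {
  counts <- parse_formula(formula)
  if (!length(setdiff(names(counts), "H"))) {
    rlang::abort("formula must contain at least one heavy atom",
                 class = "decoybench_bad_formula")
  }
  if (!s_valence %in% c(2L, 4L, 6L)) {
    rlang::abort("s_valence must be 2, 4 or 6", class = "decoybench_bad_formula")
  }
  if (!p_valence %in% c(3L, 5L)) {
    rlang::abort("p_valence must be 3 or 5", class = "decoybench_bad_formula")
  }
  structure(list(formula = counts, max_isomers = max_isomers,
                 max_rings = max_rings, allow_triple = allow_triple,
                 s_valence = as.integer(s_valence),
                 p_valence = as.integer(p_valence)),
            class = "enumeration_constraints")
}

#' Enumerate the constitutional isomers of a molecular formula
#'
#' Generates every connected heavy-atom structure (with bond orders up to 3)
#' whose implicit hydrogens sum exactly to the hydrogen count of the formula,
#' up to graph isomorphism. Output order is deterministic: isomers are sorted
#' by canonical form, and truncation at `max_isomers` cuts the generation in
#' a fixed search order, so identical inputs always give identical output.
#'
#' @param formula A formula string / named counts, or an
#'   [enumeration_constraints()] object.
#' @param ... Passed to [enumeration_constraints()] when `formula` is not
#'   already a constraints object.
#' @return An `isomer_set`: a list of [molecule()]s with attributes
#'   `formula`, `truncated` (logical) and `feasible` (FALSE when no valid
#'   isomer exists for the formula — an empty result, not an error).
#' @examples
#' length(enumerate_isomers("C4H10"))   # butane, isobutane
#' length(enumerate_isomers("C2H6O"))   # ethanol, dimethyl ether
#' @export
enumerate_isomers <- function(formula, ...) {
  cons <- if (inherits(formula, "enumeration_constraints")) formula
          else enumeration_constraints(formula, ...)
  counts <- cons$formula
  h_total <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  heavy <- counts[setdiff(names(counts), "H")]

  vmap <- .default_valences
  vmap["S"] <- cons$s_valence
  vmap["P"] <- cons$p_valence
  if (anyNA(vmap[names(heavy)])) {
    rlang::abort(paste0("unsupported element(s) in formula: ",
                        paste(names(heavy)[is.na(vmap[names(heavy)])],
                              collapse = ", ")),
                 class = "decoybench_bad_element")
  }

  elements <- rep(names(heavy), heavy)
  val <- as.integer(vmap[elements])
  ord <- order(-val, elements)
  elements <- elements[ord]
  val <- val[ord]
  n <- length(elements)

  empty_set <- function() {
    structure(list(), class = "isomer_set",
              formula = format_formula(counts), feasible = FALSE,
              truncated = FALSE)
  }

  twoB <- sum(val) - h_total
  if (twoB < 0L || twoB %% 2L != 0L) return(empty_set())
  B <- twoB %/% 2L
  if (n == 1L) {
    if (B != 0L) return(empty_set())
    m <- molecule(elements, hcount = h_total,
                  id = sprintf("%s_001", format_formula(counts)))
    return(structure(list(m), class = "isomer_set",
                     formula = format_formula(counts), feasible = TRUE,
                     truncated = FALSE))
  }
  if (B < n - 1L) return(empty_set())

  max_order <- if (cons$allow_triple) 3L else 2L
  max_edges <- n - 1L + (if (is.finite(cons$max_rings)) cons$max_rings else Inf)

  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    pairs_i <- c(pairs_i, rep(i, n - i))
    pairs_j <- c(pairs_j, (i + 1L):n)
  }
  P <- length(pairs_i)

  # element-class bookkeeping for the connected-growth symmetry rule
  class_id <- match(paste(elements, val), unique(paste(elements, val)))
  same_as_prev <- c(FALSE, class_id[-1L] == class_id[-n])

  st <- new.env(parent = emptyenv())
  st$res <- val
  st$deg <- integer(n)       # number of incident bonds (any order)
  st$orders <- integer(P)
  st$B_rem <- B
  st$E <- 0L
  st$found <- new.env(hash = TRUE, parent = emptyenv())
  st$mols <- list()
  st$truncated <- FALSE
  fml <- format_formula(counts)

  emit_leaf <- function() {
    keep <- st$orders > 0L
    bonds <- data.frame(from = pairs_i[keep], to = pairs_j[keep],
                        order = st$orders[keep])
    m <- molecule(elements, bonds = bonds, hcount = st$res, id = fml,
                  validate = FALSE)
    if (!mol_connected(m)) return(invisible())
    key <- mol_canonical(m)
    if (is.null(st$found[[key]])) {
      st$found[[key]] <- TRUE
      st$mols[[length(st$mols) + 1L]] <- m
      if (length(st$mols) >= cons$max_isomers) st$truncated <- TRUE
    }
    invisible()
  }

  descend <- function(p) {
    if (st$truncated) return(invisible())
    if (p > P) {
      if (st$B_rem == 0L) emit_leaf()
      return(invisible())
    }
    i <- pairs_i[p]; j <- pairs_j[p]
    hi <- min(max_order, st$res[i], st$res[j], st$B_rem)
    for (o in hi:0L) {
      if (o > 0L) {
        # ring budget
        if (st$E + 1L > max_edges) next
        # connected-growth: within an element class, atom j may receive its
        # first bond only after atom j-1 has one (likewise for row atom i)
        if (st$deg[j] == 0L && same_as_prev[j] && j - 1L != i &&
            st$deg[j - 1L] == 0L) next
        if (st$deg[i] == 0L && same_as_prev[i] && st$deg[i - 1L] == 0L) next
      }
      st$orders[p] <- o
      st$res[i] <- st$res[i] - o
      st$res[j] <- st$res[j] - o
      st$B_rem <- st$B_rem - o
      if (o > 0L) {
        st$deg[i] <- st$deg[i] + 1L
        st$deg[j] <- st$deg[j] + 1L
        st$E <- st$E + 1L
      }
      ok <- TRUE
      # an atom whose pair row is exhausted must already be bonded
      if (j == n && st$deg[i] == 0L) ok <- FALSE
      # remaining pairs must be able to absorb the remaining bond budget
      if (ok && st$B_rem > 0L) {
        rem_pairs <- P - p
        if (st$B_rem > max_order * rem_pairs) ok <- FALSE
        else {
          active <- unique(c(pairs_i[(p + 1L):P], pairs_j[(p + 1L):P]))
          if (st$B_rem > sum(st$res[active]) %/% 2L) ok <- FALSE
        }
      }
      if (ok) descend(p + 1L)
      st$orders[p] <- 0L
      st$res[i] <- st$res[i] + o
      st$res[j] <- st$res[j] + o
      st$B_rem <- st$B_rem + o
      if (o > 0L) {
        st$deg[i] <- st$deg[i] - 1L
        st$deg[j] <- st$deg[j] - 1L
        st$E <- st$E - 1L
      }
      if (st$truncated) break
    }
    invisible()
  }
  descend(1L)

  mols <- st$mols
  if (length(mols)) {
    keys <- vapply(mols, mol_canonical, character(1L))
    mols <- mols[order(keys)]
    for (k in seq_along(mols)) mols[[k]]$id <- sprintf("%s_%03d", fml, k)
  }
  structure(mols, class = "isomer_set", formula = fml,
            feasible = length(mols) > 0L, truncated = st$truncated)
}

#' @export
print.isomer_set <- function(x, ...) {
  cat(sprintf("<isomer_set> %s: %d isomer(s)%s%s\n",
              attr(x, "formula"), length(x),
              if (attr(x, "truncated")) " [truncated]" else "",
              if (!attr(x, "feasible")) " [no valid isomer]" else ""))
  invisible(x)
}
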