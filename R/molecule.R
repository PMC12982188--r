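#' Construct a molecule from atoms and bonds
#'
#' A molecule is a heavy-atom graph: hydrogens are carried as implicit
#' per-atom counts and only materialise on SDF export. Bond orders are
#' explicit Kekule orders (1, 2, 3); no aromaticity perception is done
#' anywhere in the package.
#'
#' @param elements Character vector of element symbols for the heavy atoms
#'   (e.g. `c("C", "C", "O")`).
#' @param bonds A data frame with integer columns `from`, `to`, `order`
#'   (order in 1:3), or `NULL` for a single-atom molecule.
#' @param charges Integer vector of formal charges, recycled to the number
#'   of atoms. Default 0.
#' @param hcount Integer vector of implicit hydrogen counts per atom, or
#'   `NULL` to fill every atom up to its default valence (standard SMILES
#'   semantics for organic-subset atoms).
#' @param id Identifier string; auto-assigned when `NULL`.
#' @param validate Check invariants (valence caps, bond sanity). Default TRUE.
#'
#' @return An object of class `molecule`.
#' @examples
#' ethanol <- molecule(c("C", "C", "O"),
#'                     bonds = data.frame(from = c(1, 2), to = c(2, 3), order = 1))
#' mol_formula(ethanol)
#' @export
molecule <- function(elements, bonds = NULL, charges = 0L, hcount = NULL,
                     id = NULL, validate = TRUE) {
  n <- length(elements)
  if (n == 0L) {
    rlang::abort("a molecule must contain at least one heavy atom",
                 class = "decoybench_empty_molecule")
  }
  elements <- as.character(elements)
  charges <- as.integer(rep_len(charges, n))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- data.frame(from = as.integer(bonds$from),
                        to = as.integer(bonds$to),
                        order = as.integer(bonds$order))
    swap <- bonds$from > bonds$to
    if (any(swap)) {
      tmp <- bonds$from[swap]
      bonds$from[swap] <- bonds$to[swap]
      bonds$to[swap] <- tmp
    }
    bonds <- bonds[order(bonds$from, bonds$to), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  deg <- bond_order_sums(n, bonds)
  if (is.null(hcount)) {
    hcount <- pmax(0L, default_valence(elements, charges) - deg)
  } else {
    hcount <- as.integer(rep_len(hcount, n))
  }
  m <- structure(
    list(element = elements, charge = charges, hcount = hcount,
         bonds = bonds, id = id %||% "mol"),
    class = "molecule"
  )
  if (validate) validate_molecule(m)
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s  %s: %d heavy atoms, %d bonds\n",
              x$id, mol_formula(x), length(x$element), nrow(x$bonds)))
  invisible(x)
}

# sum of bond orders incident to each atom
bond_order_sums <- function(n, bonds) {
  deg <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      deg[bonds$from[k]] <- deg[bonds$from[k]] + bonds$order[k]
      deg[bonds$to[k]] <- deg[bonds$to[k]] + bonds$order[k]
    }
  }
  deg
}

# Default valences of the elements the toolkit handles. Sulfur and
# phosphorus hypervalent states (S4/S6, P5) are opt-in at enumeration time.
.default_valences <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                       F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)

#' Default valence cap for an element
#'
#' Formal charge shifts the cap for the heteroatoms where that is the
#' textbook behaviour (ammonium N counts 4, alkoxide O counts 1).
#'
#' @param element Character vector of element symbols.
#' @param charge Integer vector of formal charges (recycled).
#' @return Integer vector of valence caps.
#' @export
default_valence <- function(element, charge = 0L) {
  v <- .default_valences[element]
  if (anyNA(v)) {
    rlang::abort(paste0("unsupported element(s): ",
                        paste(unique(element[is.na(v)]), collapse = ", ")),
                 class = "decoybench_bad_element")
  }
  charge <- rep_len(as.integer(charge), length(element))
  adj <- element %in% c("N", "O", "P", "S")
  v <- as.integer(v)
  v[adj] <- v[adj] + charge[adj]
  pmax(v, 0L)
}

#' Validate a molecule's structural invariants
#'
#' Checks bond endpoints, absence of self- and duplicate bonds, and the
#' valence cap (bond order sum + implicit hydrogens must not exceed the
#' element's allowed valence; sulfur may use 2/4/6 and phosphorus 3/5).
#'
#' @param m A `molecule`.
#' @return `m`, invisibly; aborts with a structured error otherwise.
#' @export
validate_molecule <- function(m) {
  n <- length(m$element)
  b <- m$bonds
  if (nrow(b)) {
    if (any(b$from < 1L | b$to < 1L | b$from > n | b$to > n)) {
      rlang::abort("bond endpoint out of range", class = "decoybench_bad_bond")
    }
    if (any(b$from == b$to)) {
      rlang::abort("self-bonds are not allowed", class = "decoybench_bad_bond")
    }
    key <- paste(b$from, b$to)
    if (anyDuplicated(key)) {
      rlang::abort("duplicate bond between one atom pair",
                   class = "decoybench_bad_bond")
    }
    if (any(b$order < 1L | b$order > 3L)) {
      rlang::abort("bond orders must be 1, 2 or 3",
                   class = "decoybench_bad_bond")
    }
  }
  if (any(m$hcount < 0L)) {
    rlang::abort("negative implicit hydrogen count",
                 class = "decoybench_bad_valence")
  }
  used <- bond_order_sums(n, b) + m$hcount
  cap <- default_valence(m$element, m$charge)
  # hypervalent states admitted for S (4, 6) and P (5)
  over <- used > cap &
    !(m$element == "S" & used %in% c(4L, 6L)) &
    !(m$element == "P" & used == 5L)
  if (any(over)) {
    i <- which(over)[1L]
    rlang::abort(
      sprintf("valence cap exceeded at atom %d (%s: %d used, cap %d)",
              i, m$element[i], used[i], cap[i]),
      class = "decoybench_bad_valence"
    )
  }
  invisible(m)
}

#' Molecular formula of a molecule
#'
#' Hill-ordered formula string (C first, then H, then remaining elements
#' alphabetically) including implicit hydrogens.
#'
#' @param m A `molecule`.
#' @return A string such as `"C2H6O"`.
#' @export
mol_formula <- function(m) {
  counts <- formula_counts(m)
  format_formula(counts)
}

# element -> count map including hydrogens
formula_counts <- function(m) {
  tab <- table(m$element)
  counts <- stats::setNames(as.integer(tab), names(tab))
  h <- sum(m$hcount)
  if (h > 0L) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  }
  counts[counts > 0L]
}

format_formula <- function(counts) {
  els <- names(counts)
  lead <- intersect(c("C", "H"), els)
  rest <- sort(setdiff(els, lead))
  ordered <- c(lead, rest)
  paste0(ordered, ifelse(counts[ordered] > 1L, counts[ordered], ""),
         collapse = "")
}

#' Parse a molecular formula string
#'
#' @param formula A formula string such as `"C4H10"` or `"C2H6O"`, or an
#'   already-named integer vector (returned unchanged).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H14")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(stats::setNames(as.integer(formula), names(formula)))
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    rlang::abort(sprintf("cannot parse formula '%s'", formula),
                 class = "decoybench_bad_formula")
  }
  mm <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  parts <- regmatches(formula, list(mm))[[1L]]
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  out <- stats::setNames(integer(0), character(0))
  for (i in seq_along(el)) {
    prev <- if (el[i] %in% names(out)) out[[el[i]]] else 0L
    out[el[i]] <- prev + ct[i]
  }
  out
}

#' Atoms of a molecule as a tibble
#'
#' @param m A `molecule`.
#' @return A tibble with columns `atom`, `element`, `charge`, `hcount`.
#' @export
mol_atoms <- function(m) {
  tibble::tibble(atom = seq_along(m$element), element = m$element,
                 charge = m$charge, hcount = m$hcount)
}

#' Bonds of a molecule as a tibble
#'
#' @param m A `molecule`.
#' @return A tibble with columns `from`, `to`, `order`.
#' @export
mol_bonds <- function(m) tibble::as_tibble(m$bonds)

# igraph view of the heavy-atom skeleton (simple graph, one edge per bonded
# pair regardless of order)
mol_graph <- function(m) {
  igraph::graph_from_data_frame(
    m$bonds[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(m$element))
  )
}

mol_connected <- function(m) {
  if (length(m$element) == 1L) return(TRUE)
  if (nrow(m$bonds) < length(m$element) - 1L) return(FALSE)
  igraph::is_connected(mol_graph(m))
}

#' Canonical form of a molecule
#'
#' A string invariant under atom renumbering: two molecules have the same
#' canonical form if and only if their heavy-atom graphs are isomorphic with
#' matching element labels, formal charges, implicit hydrogen counts and
#' bond orders. Built on a BLISS canonical labeling of a vertex-coloured
#' expansion in which every bond is represented by an auxiliary vertex
#' coloured by its order.
#'
#' @param m A `molecule`.
#' @return A canonical string.
#' @export
mol_canonical <- function(m) {
  n <- length(m$element)
  akey <- paste0(m$element, ifelse(m$charge != 0L, sprintf("%+d", m$charge), ""),
                 "H", m$hcount)
  nb <- nrow(m$bonds)
  if (n == 1L) return(akey)
  bkey <- paste0("~", m$bonds$order)
  keys <- c(akey, bkey)
  lev <- sort(unique(keys))
  colors <- match(keys, lev)
  edges <- rbind(cbind(m$bonds$from, n + seq_len(nb)),
                 cbind(m$bonds$to, n + seq_len(nb)))
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  gg <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gg)
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  ckey <- lev[colors][order(perm)]
  paste(paste(ckey, collapse = ","),
        paste(el[, 1L], el[, 2L], sep = "-", collapse = ","),
        sep = "|")
}

#' Test two molecules for constitutional identity
#'
#' Graph isomorphism with matching element labels, charges, implicit
#' hydrogen counts and bond orders (i.e. same constitution; stereochemistry
#' is outside the model).
#'
#' @param a,b Molecules.
#' @return TRUE or FALSE.
#' @export
mol_isomorphic <- function(a, b) {
  if (length(a$element) != length(b$element)) return(FALSE)
  if (nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  identical(mol_canonical(a), mol_canonical(b))
}
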