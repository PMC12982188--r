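# SMILES reading and writing.
#
# The in-package grammar is the constitutional (Kekule) subset: organic-subset
# and bracket atoms, bond orders -, =, #, branches, ring closures (including
# %nn), formal charges and explicit bracket hydrogen counts. Stereo markers
# (/ \ @) are dropped on input since the model carries constitution only.
# Aromatic (lowercase) input is kekulized through Open Babel (ChemmineOB)
# before parsing, keeping the internal model free of aromaticity perception.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

smiles_error <- function(msg, token, pos) {
  rlang::abort(sprintf("SMILES parse error at position %d ('%s'): %s",
                       pos, token, msg),
               class = "decoybench_parse_error")
}

#' Parse a SMILES string
#'
#' @param text A single SMILES string (Kekule form; aromatic lowercase input
#'   is kekulized via Open Babel when the ChemmineOB package is available).
#' @param id Identifier for the molecule; defaults to the SMILES itself.
#' @return A [molecule()].
#' @examples
#' mol_from_smiles("CCO")
#' mol_from_smiles("C1=CC=CC=C1")
#' @export
mol_from_smiles <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    rlang::abort("empty SMILES string", class = "decoybench_parse_error")
  }
  if (grepl("\\.", text)) {
    smiles_error("disconnected (multi-component) SMILES is not supported",
                 ".", regexpr("\\.", text)[1L])
  }
  # strip stereo bond markers; constitution only
  plain <- gsub("[/\\\\]", "", text)
  if (smiles_is_aromatic(plain)) {
    return(kekulize_smiles(plain, id = id %||% text))
  }
  parse_kekule_smiles(plain, id = id %||% text)
}

# lowercase aromatic atoms outside brackets, aromatic bond, or aromatic
# bracket atoms
smiles_is_aromatic <- function(text) {
  stripped <- gsub("\\[[^]]*\\]", "", text)
  grepl("[bcnops]", stripped) || grepl(":", stripped) ||
    grepl("\\[[0-9]*[bcnops]", text)
}

kekulize_smiles <- function(text, id) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    rlang::abort(
      "aromatic SMILES input needs the ChemmineOB package for kekulization; supply a Kekule SMILES instead",
      class = "decoybench_parse_error"
    )
  }
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(text, "\n"))
  m <- parse_sdf_block(strsplit(sdf, "\n", fixed = TRUE)[[1L]])
  m$id <- id
  m
}

parse_kekule_smiles <- function(text, id) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  np <- length(chars)
  element <- character()
  charge <- integer()
  hexp <- integer()     # explicit bracket H count (NA = organic subset rules)
  bonds_from <- integer(); bonds_to <- integer(); bonds_order <- integer()
  prev <- NA_integer_
  pending <- NA_integer_
  stack <- integer()
  rings <- list()       # closure label -> list(atom, order)

  add_atom <- function(el, chg, h) {
    element[length(element) + 1L] <<- el
    charge[length(charge) + 1L] <<- chg
    hexp[length(hexp) + 1L] <<- h
    j <- length(element)
    if (!is.na(prev)) {
      bonds_from[length(bonds_from) + 1L] <<- prev
      bonds_to[length(bonds_to) + 1L] <<- j
      bonds_order[length(bonds_order) + 1L] <<- if (is.na(pending)) 1L else pending
    }
    prev <<- j
    pending <<- NA_integer_
    j
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) smiles_error("branch before any atom", ch, i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) smiles_error("unmatched ')'", ch, i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#")) {
      pending <- c(`-` = 1L, `=` = 2L, `#` = 3L)[[ch]]
      i <- i + 1L
    } else if (ch == ":") {
      smiles_error("aromatic bond in Kekule parser", ch, i)
    } else if (ch == "$") {
      smiles_error("quadruple bonds are not supported", ch, i)
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > np || !grepl("^[0-9][0-9]$",
                                  paste0(chars[i + 1L], chars[i + 2L]))) {
          smiles_error("'%' must be followed by two digits", ch, i)
        }
        lab <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (is.na(prev)) smiles_error("ring closure before any atom", lab, i)
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- list(atom = prev, order = pending)
      } else {
        opened <- rings[[lab]]
        ord <- if (!is.na(pending)) pending else opened$order
        if (!is.na(pending) && !is.na(opened$order) && pending != opened$order) {
          smiles_error("conflicting bond orders at ring closure", lab, i)
        }
        if (opened$atom == prev) smiles_error("ring closure to same atom", lab, i)
        bonds_from[length(bonds_from) + 1L] <- opened$atom
        bonds_to[length(bonds_to) + 1L] <- prev
        bonds_order[length(bonds_order) + 1L] <- if (is.na(ord)) 1L else ord
        rings[[lab]] <- NULL
      }
      pending <- NA_integer_
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(np) > i)[1L]
      if (is.na(close)) smiles_error("unterminated bracket atom", ch, i)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(body, i)
      add_atom(at$element, at$charge, at$hcount)
      i <- close + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < np) paste0(ch, chars[i + 1L]) else ch
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, NA_integer_)
        i <- i + 2L
      } else if (ch %in% .organic_subset) {
        add_atom(ch, 0L, NA_integer_)
        i <- i + 1L
      } else {
        smiles_error("element must be written in brackets", ch, i)
      }
    } else {
      smiles_error("unexpected character", ch, i)
    }
  }
  if (length(stack)) smiles_error("unclosed branch '('", "(", np)
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1L))]
  if (length(open_rings)) {
    smiles_error(paste0("unclosed ring bond(s): ",
                        paste(open_rings, collapse = ", ")), "ring", np)
  }
  if (!length(element)) smiles_error("no atoms found", text, 1L)

  bonds <- data.frame(from = bonds_from, to = bonds_to, order = bonds_order)
  n <- length(element)
  deg <- bond_order_sums(n, bonds)
  h <- ifelse(is.na(hexp),
              pmax(0L, default_valence(element, charge) - deg),
              hexp)
  m <- molecule(element, bonds = bonds, charges = charge,
                hcount = as.integer(h), id = id)
  if (!mol_connected(m)) {
    rlang::abort("SMILES describes a disconnected graph",
                 class = "decoybench_parse_error")
  }
  m
}

parse_bracket_atom <- function(body, pos) {
  rx <- "^([0-9]*)([A-Z][a-z]?|[a-z])(@{0,2})(H([0-9]*))?(([+-])([0-9]*)|(\\+\\+)|(--))?$"
  mm <- regexec(rx, body)[[1L]]
  if (mm[1L] == -1L) smiles_error("cannot parse bracket atom", body, pos)
  gr <- regmatches(body, list(regexec(rx, body)[[1L]]))[[1L]]
  el <- gr[3L]
  if (grepl("^[a-z]", el)) smiles_error("aromatic bracket atom", body, pos)
  h <- if (nzchar(gr[5L])) {
    if (nzchar(gr[6L])) as.integer(gr[6L]) else 1L
  } else 0L
  chg <- 0L
  if (nzchar(gr[8L])) {
    sign <- if (gr[8L] == "+") 1L else -1L
    mag <- if (nzchar(gr[9L])) as.integer(gr[9L]) else 1L
    chg <- sign * mag
  } else if (nzchar(gr[10L])) {
    chg <- 2L
  } else if (nzchar(gr[11L])) {
    chg <- -2L
  }
  if (el == "H") smiles_error("bare hydrogen atoms are not modelled", body, pos)
  list(element = el, charge = chg, hcount = h)
}

#' Write a molecule as a SMILES string
#'
#' Emits a Kekule SMILES (explicit bond orders, no aromatic lowercase, no
#' stereo descriptors). Round-trip safe: the output re-parses to a molecule
#' isomorphic to the input with identical element, charge and order labels.
#'
#' @param m A [molecule()].
#' @return A SMILES string.
#' @examples
#' mol_to_smiles(mol_from_smiles("C1=CC=CC=C1"))
#' @export
mol_to_smiles <- function(m) {
  validate_molecule(m)
  n <- length(m$element)
  if (n == 0L) rlang::abort("empty molecule", class = "decoybench_empty_molecule")
  adj <- vector("list", n)
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      f <- m$bonds$from[k]; t <- m$bonds$to[k]
      adj[[f]] <- rbind(adj[[f]], c(t, m$bonds$order[k]))
      adj[[t]] <- rbind(adj[[t]], c(f, m$bonds$order[k]))
    }
  }
  visited <- logical(n)
  closure_at <- vector("list", n)   # per atom: list of c(label, order, open)
  tree_children <- vector("list", n)
  parent <- rep(NA_integer_, n)
  ring_n <- 0L

  # iterative DFS to classify tree vs ring-closure bonds
  stack2 <- 1L
  visited[1L] <- TRUE
  order_seen <- 1L
  seen_edge <- new.env(hash = TRUE)
  while (length(stack2)) {
    v <- stack2[length(stack2)]
    stack2 <- stack2[-length(stack2)]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1L]; o <- nb[r, 2L]
      ekey <- paste(min(u, v), max(u, v))
      if (!is.null(seen_edge[[ekey]])) next
      if (!visited[u]) {
        seen_edge[[ekey]] <- TRUE
        visited[u] <- TRUE
        parent[u] <- v
        tree_children[[v]] <- rbind(tree_children[[v]], c(u, o))
        stack2 <- c(stack2, u)
      } else {
        seen_edge[[ekey]] <- TRUE
        ring_n <- ring_n + 1L
        closure_at[[v]] <- c(closure_at[[v]], list(c(ring_n, o, 1L)))
        closure_at[[u]] <- c(closure_at[[u]], list(c(ring_n, o, 0L)))
      }
    }
  }
  if (!all(visited)) {
    rlang::abort("molecule graph is disconnected; cannot write a single SMILES",
                 class = "decoybench_write_error")
  }

  bond_sym <- c("", "=", "#")
  ring_label <- function(lab) if (lab <= 9L) as.character(lab) else sprintf("%%%02d", lab)
  deg <- bond_order_sums(n, m$bonds)
  atom_token <- function(v) {
    el <- m$element[v]
    default_h <- max(0L, default_valence(el, m$charge[v]) - deg[v])
    if (el %in% .organic_subset && m$charge[v] == 0L && m$hcount[v] == default_h) {
      el
    } else {
      h <- m$hcount[v]
      hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
      cs <- if (m$charge[v] == 0L) "" else if (m$charge[v] == 1L) "+"
            else if (m$charge[v] == -1L) "-" else sprintf("%+d", m$charge[v])
      paste0("[", el, hs, cs, "]")
    }
  }

  emit <- function(v) {
    out <- atom_token(v)
    for (cl in closure_at[[v]]) {
      out <- paste0(out,
                    if (cl[3L] == 1L) bond_sym[cl[2L]] else "",
                    ring_label(cl[1L]))
    }
    ch <- tree_children[[v]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (r in seq_len(nc)) {
        sub <- paste0(bond_sym[ch[r, 2L]], emit(ch[r, 1L]))
        out <- paste0(out, if (r < nc) paste0("(", sub, ")") else sub)
      }
    }
    out
  }
  emit(1L)
}
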