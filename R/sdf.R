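# SDF / MOL V2000 reading and writing.
#
# Import collapses explicit hydrogen atoms into implicit per-atom counts and
# fills the remainder up to default valence (the usual convention for
# hydrogen-suppressed molfiles); `M  CHG` lines take precedence over the
# legacy atom-block charge column. Export materialises hydrogens as explicit
# atoms, which is what downstream docking preparation tools expect.

#' Read molecules from an SDF (V2000) file
#'
#' @param path Path to a multi-record SDF file.
#' @return A list of [molecule()] objects, named by their record titles.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    block <- block[cumsum(trimws(block) == "$$$$") == 0L]
    if (!any(nzchar(trimws(block)))) next
    mols[[length(mols) + 1L]] <- parse_sdf_block(block)
  }
  names(mols) <- vapply(mols, function(m) m$id, character(1L))
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output path.
#' @param explicit_h Materialise implicit hydrogens as explicit atoms
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, explicit_h = TRUE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  txt <- vapply(mols, mol_to_sdf_block, character(1L), explicit_h = explicit_h)
  writeLines(paste0(txt, "$$$$"), path)
  invisible(path)
}

sdf_error <- function(msg, line_no) {
  rlang::abort(sprintf("SDF parse error at block line %d: %s", line_no, msg),
               class = "decoybench_parse_error")
}

parse_sdf_block <- function(block) {
  if (length(block) < 4L) sdf_error("molfile block too short", length(block))
  title <- trimws(block[1L])
  counts <- block[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds)) sdf_error("bad counts line", 4L)
  if (natoms < 1L) sdf_error("molfile contains no atoms", 4L)
  if (length(block) < 4L + natoms + nbonds) {
    sdf_error("block shorter than counts line promises", length(block))
  }
  atom_lines <- block[5L:(4L + natoms)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  ccode <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  ccode[is.na(ccode)] <- 0L
  # legacy charge codes: 1=+3 2=+2 3=+1 5=-1 6=-2 7=-3 (4 = radical, ignored)
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- ifelse(ccode %in% names2int(legacy),
                   legacy[as.character(ccode)], 0L)
  charge[is.na(charge)] <- 0L

  from <- integer(nbonds); to <- integer(nbonds); ord <- integer(nbonds)
  if (nbonds > 0L) {
    bond_lines <- block[(5L + natoms):(4L + natoms + nbonds)]
    from <- as.integer(substr(bond_lines, 1L, 3L))
    to <- as.integer(substr(bond_lines, 4L, 6L))
    ord <- as.integer(substr(bond_lines, 7L, 9L))
    if (anyNA(from) || anyNA(to) || anyNA(ord)) {
      sdf_error("bad bond line", 5L + natoms)
    }
    if (any(ord == 4L)) {
      sdf_error("aromatic bond type 4 is not supported; supply a Kekule molfile",
                5L + natoms)
    }
  }

  prop <- block[-seq_len(4L + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", prop, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, natoms)  # M CHG supersedes the atom-block column
    for (ln in chg_lines) {
      nn <- as.integer(substr(ln, 7L, 9L))
      for (k in seq_len(nn)) {
        off <- 10L + (k - 1L) * 8L
        ai <- as.integer(substr(ln, off, off + 3L))
        av <- as.integer(substr(ln, off + 4L, off + 7L))
        if (is.na(ai) || ai < 1L || ai > natoms) sdf_error("bad M CHG entry", 1L)
        charge[ai] <- av
      }
    }
  }

  bonds <- data.frame(from = from, to = to, order = ord)
  absorb_explicit_h(element, charge, bonds, id = if (nzchar(title)) title else "sdf_mol")
}

names2int <- function(x) as.integer(names(x))

# Collapse explicit hydrogens into implicit counts on the heavy atoms, then
# fill the remaining free valence with implicit hydrogens.
absorb_explicit_h <- function(element, charge, bonds, id) {
  n <- length(element)
  is_h <- element == "H"
  if (all(is_h)) {
    rlang::abort("molecule consists only of hydrogen atoms",
                 class = "decoybench_parse_error")
  }
  hexplicit <- integer(n)
  drop_bond <- logical(nrow(bonds))
  if (any(is_h)) {
    hdeg <- integer(n)
    for (k in seq_len(nrow(bonds))) {
      f <- bonds$from[k]; t <- bonds$to[k]
      if (is_h[f] && is_h[t]) {
        rlang::abort("H-H bond found; molecular hydrogen is not modelled",
                     class = "decoybench_parse_error")
      }
      if (is_h[f] || is_h[t]) {
        if (bonds$order[k] != 1L) {
          rlang::abort("hydrogen with non-single bond",
                       class = "decoybench_parse_error")
        }
        heavy <- if (is_h[f]) t else f
        hatom <- if (is_h[f]) f else t
        hdeg[hatom] <- hdeg[hatom] + 1L
        hexplicit[heavy] <- hexplicit[heavy] + 1L
        drop_bond[k] <- TRUE
      }
    }
    if (any(hdeg[is_h] != 1L)) {
      rlang::abort("explicit hydrogen without exactly one heavy-atom bond",
                   class = "decoybench_parse_error")
    }
    if (any(charge[is_h] != 0L)) {
      rlang::abort("charged explicit hydrogen is not supported",
                   class = "decoybench_parse_error")
    }
  }
  keep <- !is_h
  remap <- cumsum(keep)
  bonds <- bonds[!drop_bond, , drop = FALSE]
  bonds$from <- remap[bonds$from]
  bonds$to <- remap[bonds$to]
  element <- element[keep]
  charge <- charge[keep]
  hexplicit <- hexplicit[keep]
  nh <- length(element)
  deg <- bond_order_sums(nh, bonds)
  hfill <- pmax(0L, default_valence(element, charge) - deg - hexplicit)
  molecule(element, bonds = bonds, charges = charge,
           hcount = hexplicit + hfill, id = id)
}

mol_to_sdf_block <- function(m, explicit_h = TRUE) {
  validate_molecule(m)
  element <- m$element
  charge <- m$charge
  bonds <- m$bonds
  if (explicit_h) {
    nheavy <- length(element)
    for (i in seq_len(nheavy)) {
      nh <- m$hcount[i]
      if (nh > 0L) {
        for (k in seq_len(nh)) {
          element <- c(element, "H")
          charge <- c(charge, 0L)
          bonds <- rbind(bonds, data.frame(from = i, to = length(element),
                                           order = 1L))
        }
      }
    }
  }
  n <- length(element)
  header <- c(m$id, "  decoybench", "")
  countsl <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, element)
  bl <- if (nrow(bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order)
  } else character(0)
  props <- character(0)
  chg_idx <- which(charge != 0L)
  while (length(chg_idx)) {
    take <- utils::head(chg_idx, 8L)
    chg_idx <- chg_idx[-seq_along(take)]
    props <- c(props, paste0(
      sprintf("M  CHG%3d", length(take)),
      paste0(sprintf("%4d%4d", take, charge[take]), collapse = "")
    ))
  }
  paste0(paste(c(header, countsl, atoms, bl, props, "M  END"), collapse = "\n"),
         "\n")
}
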