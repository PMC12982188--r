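# Molecular property calculators used for decoy/active property matching.

# IUPAC 2021 standard atomic weights (abridged)
.atomic_masses <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                    Br = 79.904, I = 126.904)

#' Compute a property table for molecules
#'
#' One row per molecule with the descriptors used for active/decoy property
#' matching: molecular weight, Hill formula, hydrogen bond donor and acceptor
#' counts, rotatable bonds, net formal charge and ring count.
#'
#' Conventions (deliberately simple and pinned by the test suite):
#' * donors: N or O atoms bearing at least one hydrogen;
#' * acceptors: every N and O atom; with `amide_rules = TRUE`, amide
#'   nitrogens and pyrrole-type ring nitrogens are excluded;
#' * rotatable bonds: single, non-ring bonds whose two ends both have
#'   heavy-atom degree >= 2; with `amide_rules = TRUE`, amide C-N bonds are
#'   excluded as well;
#' * ring count: number of independent rings (cyclomatic number);
#' * weight: IUPAC 2021 standard atomic masses, reported to 2 decimals.
#'
#' @param mols A [molecule()] or list of molecules.
#' @param amide_rules Apply the amide/pyrrole exclusions described above
#'   (default FALSE).
#' @return A tibble with columns `id`, `mw`, `formula`, `hbd`, `hba`,
#'   `rotors`, `charge`, `rings`.
#' @examples
#' compute_properties(mol_from_smiles("CCO"))
#' @export
compute_properties <- function(mols, amide_rules = FALSE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  purrr::map_dfr(mols, mol_property_row, amide_rules = amide_rules)
}

mol_property_row <- function(m, amide_rules = FALSE) {
  validate_molecule(m)
  counts <- formula_counts(m)
  mw <- round(sum(.atomic_masses[names(counts)] * counts), 2L)
  el <- m$element
  is_no <- el %in% c("N", "O")
  hbd <- sum(is_no & m$hcount >= 1L)
  hba_mask <- is_no
  b <- m$bonds
  heavy_deg <- tabulate(c(b$from, b$to), nbins = length(el))

  if (amide_rules && nrow(b)) {
    carbonyl_c <- unique(c(
      b$from[b$order == 2L & el[b$from] == "C" & el[b$to] == "O"],
      b$to[b$order == 2L & el[b$to] == "C" & el[b$from] == "O"]
    ))
    amide_n <- unique(c(
      b$to[b$order == 1L & el[b$to] == "N" & b$from %in% carbonyl_c],
      b$from[b$order == 1L & el[b$from] == "N" & b$to %in% carbonyl_c]
    ))
    hba_mask[amide_n] <- FALSE
    hba_mask[pyrrole_type_n(m)] <- FALSE
  }
  hba <- sum(hba_mask)

  rotors <- 0L
  amide_bond <- logical(nrow(b))
  if (nrow(b)) {
    in_ring <- bonds_in_ring(m)
    if (amide_rules) {
      carbonyl_c <- unique(c(
        b$from[b$order == 2L & el[b$from] == "C" & el[b$to] == "O"],
        b$to[b$order == 2L & el[b$to] == "C" & el[b$from] == "O"]
      ))
      amide_bond <- b$order == 1L &
        ((el[b$from] == "N" & b$to %in% carbonyl_c) |
           (el[b$to] == "N" & b$from %in% carbonyl_c))
    }
    rotors <- sum(b$order == 1L & !in_ring & !amide_bond &
                    heavy_deg[b$from] >= 2L & heavy_deg[b$to] >= 2L)
  }

  tibble::tibble(id = m$id, mw = mw, formula = format_formula(counts),
                 hbd = hbd, hba = hba, rotors = as.integer(rotors),
                 charge = sum(m$charge), rings = ring_count(m))
}

# ring nitrogens with only single bonds adjacent to an in-ring double bond
# (the pyrrole motif, identified without aromaticity perception)
pyrrole_type_n <- function(m) {
  b <- m$bonds
  if (!nrow(b)) return(integer(0))
  in_ring <- bonds_in_ring(m)
  n_atoms <- length(m$element)
  order_by_atom <- function(i) b$order[b$from == i | b$to == i]
  ring_atoms <- unique(c(b$from[in_ring], b$to[in_ring]))
  dbl_ring_atoms <- unique(c(b$from[in_ring & b$order == 2L],
                             b$to[in_ring & b$order == 2L]))
  out <- integer(0)
  for (i in seq_len(n_atoms)) {
    if (m$element[i] != "N" || !(i %in% ring_atoms)) next
    if (any(order_by_atom(i) != 1L)) next
    nbrs <- c(b$to[b$from == i], b$from[b$to == i])
    if (any(nbrs %in% dbl_ring_atoms)) out <- c(out, i)
  }
  out
}
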