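#' Parse a molecular structure from text
#'
#' Format-dispatching front end over [mol_from_smiles()] and the SDF reader.
#'
#' @param text A SMILES string or the text of an SDF/MOL V2000 block.
#' @param format `"smiles"` or `"sdf"`.
#' @param id Optional identifier override.
#' @return A [molecule()].
#' @examples
#' parse_structure("CCO", "smiles")
#' @export
parse_structure <- function(text, format = c("smiles", "sdf"), id = NULL) {
  format <- match.arg(format)
  m <- switch(format,
    smiles = mol_from_smiles(text, id = id),
    sdf = {
      lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
      parse_sdf_block(lines)
    }
  )
  if (!is.null(id)) m$id <- id
  m
}

#' Serialise a molecule to text
#'
#' @param m A [molecule()].
#' @param format `"smiles"` or `"sdf"` (SDF output carries explicit
#'   hydrogens).
#' @return A character scalar in the requested format.
#' @export
write_structure <- function(m, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  switch(format,
    smiles = mol_to_smiles(m),
    sdf = paste0(mol_to_sdf_block(m, explicit_h = TRUE), "$$$$\n")
  )
}

#' Write a property report CSV
#'
#' One row per molecule: `id, mw, formula, hbd, hba, rotors, charge, rings`.
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output CSV path.
#' @param amide_rules Passed to [compute_properties()].
#' @return The property tibble, invisibly.
#' @export
write_property_report <- function(mols, path, amide_rules = FALSE) {
  props <- compute_properties(mols, amide_rules = amide_rules)
  readr::write_csv(props, path)
  invisible(props)
}

# CSV with '# key=value' header comment lines recording provenance
write_stamped_csv <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("decoybench ",
                               as.character(utils::packageVersion("decoybench")))),
            meta)
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1L)))
  writeLines(c(hdr, sub("\n$", "", readr::format_csv(df))), path)
  invisible(path)
}

#' Read a decoybench CSV, skipping provenance header comments
#'
#' @param path Path to a CSV written by the package (lines starting with
#'   `#` are provenance metadata).
#' @return A tibble.
#' @export
read_bench_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
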