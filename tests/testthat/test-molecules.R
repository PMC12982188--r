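test_that("SMILES parsing fills implicit hydrogens to standard valence", {
  eth <- mol_from_smiles("CCO")
  expect_length(eth$element, 3L)
  expect_identical(mol_formula(eth), "C2H6O")

  benz <- mol_from_smiles("C1=CC=CC=C1")
  expect_identical(mol_formula(benz), "C6H6")
  expect_identical(benz$hcount, rep(1L, 6L))
  expect_identical(sort(mol_bonds(benz)$order), c(1L, 1L, 1L, 2L, 2L, 2L))

  # bracket atoms: explicit hydrogen counts and charges are taken as written
  ammonium <- mol_from_smiles("[NH4+]")
  expect_identical(ammonium$hcount, 4L)
  expect_identical(sum(ammonium$charge), 1L)
})

test_that("SDF blocks with charge property lines parse to the annotated net charge", {
  skip_if_not_installed("ChemmineOB")
  # independent structure generator: Open Babel writes the block, we read it
  smi <- "CC(=O)[O-]"
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
  m <- parse_structure(sdf, "sdf")
  expect_identical(sum(m$charge), -1L)
  mol <- ChemmineOB::forEachMol("SDF", sdf, identity)[[1L]]
  ob_formula <- sub("-$", "", ChemmineOB::prop_OB(mol)$formula)
  expect_identical(mol_formula(m), ob_formula)
})

test_that("parse/write round trips preserve the labeled graph", {
  panel <- c("CCO", "CC(C)=O", "C1=CC=CC=C1", "C(#N)CC(=O)O", "CC(=O)[O-]",
             "[NH4+]", "ClC(Br)I", "C1CC1CC#C", "O=S(=O)(O)O", "C1=CC2=CC=CC2=C1")
  for (smi in panel) {
    m <- mol_from_smiles(smi)
    back_smi <- mol_from_smiles(mol_to_smiles(m))
    expect_true(oracle_isomorphic(m, back_smi), label = paste("SMILES", smi))
    expect_true(mol_isomorphic(m, back_smi), label = paste("SMILES", smi))
    back_sdf <- parse_structure(write_structure(m, "sdf"), "sdf")
    expect_true(oracle_isomorphic(m, back_sdf), label = paste("SDF", smi))
  }
  # sulfuric acid exercises the hypervalent sulfur path
  expect_identical(mol_formula(mol_from_smiles("O=S(=O)(O)O")), "H2O4S")
})

test_that("round trips hold over enumerator-generated molecules", {
  pool <- enumerate_isomers("C4H6O")
  withr::with_seed(11, {
    for (m in pool[sample.int(length(pool), 12L)]) {
      expect_true(mol_isomorphic(m, mol_from_smiles(mol_to_smiles(m))))
      expect_true(mol_isomorphic(m, parse_structure(write_structure(m, "sdf"),
                                                    "sdf")))
    }
  })
})

test_that("multi-record SDF files round trip through disk", {
  mols <- list(mol_from_smiles("CCO", id = "ethanol"),
               mol_from_smiles("CC(=O)[O-]", id = "acetate"),
               mol_from_smiles("C1CCCCC1", id = "cyclohexane"))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, f)
  back <- read_sdf(f)
  expect_named(back, c("ethanol", "acetate", "cyclohexane"))
  for (i in seq_along(mols)) expect_true(mol_isomorphic(mols[[i]], back[[i]]))
})

test_that("malformed input gives structured errors naming the offence", {
  expect_error(mol_from_smiles("C(C"), class = "decoybench_parse_error")
  expect_error(mol_from_smiles("C1CC"), class = "decoybench_parse_error")
  expect_error(mol_from_smiles("CC.O"), class = "decoybench_parse_error")
  expect_error(mol_from_smiles("C%1"), class = "decoybench_parse_error")
  expect_error(mol_from_smiles(""), class = "decoybench_parse_error")
  expect_error(mol_from_smiles("CXQ"), class = "decoybench_parse_error")
  # valence violation is rejected with the atom index in the message
  err <- expect_error(
    molecule(c("C", "F"), bonds = data.frame(from = 1, to = 2, order = 2)),
    class = "decoybench_bad_valence"
  )
  expect_match(conditionMessage(err), "atom 2")
  expect_error(molecule(character(0)), class = "decoybench_empty_molecule")
  expect_error(write_structure(mol_from_smiles("CC"), "mol2"))
})

test_that("property computation is invariant under atom reindexing", {
  m <- mol_from_smiles("CC(=O)NC1=CC=CC=C1O", id = "x")
  perm <- rev(seq_along(m$element))
  inv <- order(perm)
  m2 <- molecule(m$element[perm],
                 bonds = data.frame(from = inv[m$bonds$from],
                                    to = inv[m$bonds$to],
                                    order = m$bonds$order),
                 charges = m$charge[perm], hcount = m$hcount[perm], id = "x")
  expect_identical(compute_properties(m), compute_properties(m2))
  expect_true(mol_isomorphic(m, m2))
})
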