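# Hand-built molecules and fixture builders shared across tests.

# 4-membered carbon ring containing a C=C=C cumulene unit
cyclic_allene <- function() {
  decoybench::molecule(
    c("C", "C", "C", "C"),
    bonds = data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                       order = c(2, 2, 1, 1)),
    id = "cyclic_allene"
  )
}

benzene <- function() decoybench::mol_from_smiles("C1=CC=CC=C1", id = "benzene")
propadiene <- function() decoybench::mol_from_smiles("C=C=C", id = "propadiene")

# the three fixture actives of the isomer-decoy benchmark (small, distinct
# formulas with comfortably more than 25 filtered isomers each)
benchmark_actives <- function() {
  list(
    decoybench::mol_from_smiles("CCCCCCO", id = "ACT_hexanol"),
    decoybench::mol_from_smiles("CCCCCCN", id = "ACT_hexylamine"),
    decoybench::mol_from_smiles("CCCCC=O", id = "ACT_pentanal")
  )
}

# paper-shaped randomization fixture: 29 structures whose identity groups
# plant exactly 26 cross-structure binders under forced same-identity
# crossdocking with k = 25
randomization_fixture <- function(seed = 1L) {
  groups <- decoybench::degeneracy_groups(29L, 26L)
  coll <- decoybench::generate_synthetic_collection(29L, groups, seed = seed)
  pairs <- decoybench::build_randomized_pairs(coll, 25L, seed = seed,
                                              force_same_identity = TRUE)
  list(collection = coll,
       pairs = decoybench::relabel_by_identity(pairs, coll))
}

random_score_fixture <- function(seed = 1L, shift = 2, noise = 0.3,
                                 n_actives = 3L, n_decoys = 75L,
                                 replicas = 4L) {
  decoybench::generate_synthetic_scores(decoybench::synthetic_score_config(
    n_actives = n_actives, n_decoys = n_decoys, replicas = replicas,
    shift = shift, noise = noise, seed = seed
  ))
}
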