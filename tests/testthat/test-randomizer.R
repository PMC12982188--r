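test_that("small randomizations are exhaustive and self-controlled", {
  coll <- generate_synthetic_collection(3L, seed = 1L)
  pairs <- build_randomized_pairs(coll, 2L, seed = 1L)
  expect_identical(nrow(pairs), 9L)   # every ligand meets every structure
  expect_identical(sum(pairs$mode == "redock"), 3L)
  # every ligand and every protein serves as its own control
  expect_setequal(unique(pairs$ligand_id), coll$ligand_id)
  expect_setequal(unique(pairs$complex_id), coll$complex_id)
  redocks <- pairs[pairs$mode == "redock", ]
  expect_identical(redocks$ligand_id,
                   coll$ligand_id[match(redocks$complex_id, coll$complex_id)])

  only_re <- build_randomized_pairs(coll, 0L, seed = 1L)
  expect_identical(nrow(only_re), 3L)
  expect_true(all(only_re$mode == "redock"))
})

test_that("oversized crossdock requests fail with the constraint named", {
  coll <- generate_synthetic_collection(4L, seed = 1L)
  err <- expect_error(build_randomized_pairs(coll, 4L),
                      class = "decoybench_bad_input")
  expect_match(conditionMessage(err), "smaller than the collection size")
})

test_that("pair construction is deterministic under a fixed seed", {
  coll <- generate_synthetic_collection(10L, seed = 3L)
  p1 <- build_randomized_pairs(coll, 4L, seed = 99L)
  p2 <- build_randomized_pairs(coll, 4L, seed = 99L)
  expect_identical(p1, p2)
})

test_that("identity relabeling recovers same-protein crossdocks and is idempotent", {
  # two structures of one protein, one unrelated: each degenerate ligand
  # crossdocked onto its sibling structure is a true binder
  coll <- generate_synthetic_collection(3L, group_sizes = c(2L, 1L), seed = 1L)
  pairs <- build_randomized_pairs(coll, 2L, seed = 1L)
  lab <- relabel_by_identity(pairs, coll)
  cross_binders <- lab[lab$mode == "crossdock" & lab$label == "binder", ]
  expect_identical(nrow(cross_binders), 2L)
  expect_setequal(cross_binders$complex_id, coll$complex_id[1:2])
  expect_true(all(lab$label[lab$mode == "redock"] == "binder"))
  # idempotent, membership untouched
  expect_identical(relabel_by_identity(lab, coll), lab)
  expect_setequal(lab$pair_id, pairs$pair_id)
})

test_that("degeneracy-free collections have zero crossdock binders", {
  for (seed in 1:5) {
    coll <- generate_synthetic_collection(8L, seed = seed)
    lab <- relabel_by_identity(build_randomized_pairs(coll, 3L, seed = seed),
                               coll)
    expect_identical(nrow(lab[lab$mode == "crossdock" &
                                lab$label == "binder", ]), 0L)
    s <- summarize_set(lab)
    expect_identical(s$n_pairs, s$n_redock + s$n_crossdock)
    expect_identical(s$n_pairs, s$n_binder + s$n_decoy)
  }
})

test_that("user-supplied known binders extend the relation", {
  coll <- generate_synthetic_collection(4L, seed = 2L)
  pairs <- build_randomized_pairs(coll, 3L, seed = 2L)
  extra <- tibble::tibble(ligand_id = coll$ligand_id[2L],
                          uniprot_id = coll$uniprot_id[1L])
  lab <- relabel_by_identity(pairs, coll, known_binders = extra)
  hit <- lab[lab$complex_id == coll$complex_id[1L] &
               lab$ligand_id == coll$ligand_id[2L], ]
  expect_true(all(hit$label == "binder"))
})

test_that("pairs against unknown structures are refused with the ids listed", {
  coll <- generate_synthetic_collection(3L, seed = 1L)
  pairs <- build_randomized_pairs(coll, 1L, seed = 1L)
  pairs$complex_id[1L] <- "CPX9999"
  err <- expect_error(relabel_by_identity(pairs, coll),
                      class = "decoybench_bad_input")
  expect_match(conditionMessage(err), "CPX9999")
})

test_that("set summaries report the rounded decoy:active ratio", {
  pairs <- tibble::tibble(
    pair_id = sprintf("p%02d", 1:78),
    complex_id = "c", ligand_id = sprintf("l%02d", 1:78),
    mode = c(rep("redock", 3L), rep("crossdock", 75L)),
    label = c(rep("binder", 3L), rep("decoy", 75L)),
    provenance = ""
  )
  s <- summarize_set(pairs)
  expect_identical(s$ratio, "1:25")
  all_re <- summarize_set(pairs[pairs$mode == "redock", ])
  expect_identical(all_re$n_binder, 3L)
  expect_identical(all_re$n_decoy, 0L)
})

test_that("collections survive the CSV round trip with provenance headers", {
  coll <- generate_synthetic_collection(6L, group_sizes = c(3L, 2L, 1L),
                                        seed = 4L)
  f <- withr::local_tempfile(fileext = ".csv")
  decoybench:::write_stamped_csv(coll, f, meta = list(seed = 4L))
  expect_match(readLines(f, n = 1L), "^# tool=decoybench")
  back <- read_collection(f)
  expect_identical(as.data.frame(back), as.data.frame(coll))
  manifest <- docking_manifest(build_randomized_pairs(coll, 2L, seed = 1L),
                               coll)
  expect_length(manifest, 18L)
  expect_match(manifest[1L], "reference_ligand=")
})
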