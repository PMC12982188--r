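test_that("cumulated double bonds in small rings are rejected, benzene kept", {
  res <- apply_sanity_filters(list(cyclic_allene(), benzene()))
  kept_ids <- vapply(res$molecules, function(m) m$id, character(1L))
  expect_identical(kept_ids, "benzene")
  expect_identical(res$report$rejections$id, "cyclic_allene")
  expect_identical(res$report$rejections$rule, "cumulene_in_ring")
})

test_that("linear allenes pass by default and fall to the strict rule", {
  default <- apply_sanity_filters(list(propadiene()))
  expect_length(default$molecules, 1L)
  strict <- apply_sanity_filters(list(propadiene()),
                                 sanity_rules(cumulene_any = TRUE))
  expect_length(strict$molecules, 0L)
  expect_identical(strict$report$rejections$rule, "cumulene_any")
})

test_that("ring-size threshold scopes the cumulene rule", {
  # a 10-membered ring cumulene is allowed at the default threshold of 8
  big_ring <- molecule(rep("C", 10L),
                       bonds = data.frame(from = 1:10,
                                          to = c(2:10, 1L),
                                          order = c(2L, 2L, rep(1L, 8L))),
                       id = "cyclodecadiene_cumulated")
  expect_length(apply_sanity_filters(list(big_ring))$molecules, 1L)
  tight <- apply_sanity_filters(list(big_ring),
                                sanity_rules(max_ring_size = 12L))
  expect_length(tight$molecules, 0L)
})

test_that("triple bonds in small rings are rejected only when enabled", {
  cycloheptyne <- mol_from_smiles("C1CCCCC#C1", id = "cycloheptyne")
  expect_length(apply_sanity_filters(list(cycloheptyne))$molecules, 1L)
  strict <- apply_sanity_filters(list(cycloheptyne),
                                 sanity_rules(triple_in_ring = TRUE))
  expect_identical(strict$report$rejections$rule, "triple_in_ring")
  # a plain alkyne is never touched by the ring rule
  expect_length(apply_sanity_filters(list(mol_from_smiles("CC#C")),
                                     sanity_rules(triple_in_ring = TRUE))$molecules,
                1L)
})

test_that("filtering is idempotent and accounting is exact", {
  pool <- enumerate_isomers("C5H4", max_isomers = 120L)
  once <- apply_sanity_filters(pool)
  expect_identical(once$report$n_input,
                   once$report$n_kept + nrow(once$report$rejections))
  expect_gt(nrow(once$report$rejections), 0L)  # C5H4 is cumulene-rich
  twice <- apply_sanity_filters(once$molecules)
  expect_identical(vapply(twice$molecules, function(m) m$id, character(1L)),
                   vapply(once$molecules, function(m) m$id, character(1L)))
  expect_identical(nrow(twice$report$rejections), 0L)
  # every rejection names exactly one rule
  expect_true(all(once$report$rejections$rule %in%
                    c("cumulene_in_ring", "cumulene_any", "triple_in_ring")))
})

test_that("first matching rule claims the rejection", {
  strict <- sanity_rules(cumulene_any = TRUE)
  res <- apply_sanity_filters(list(cyclic_allene(), propadiene()), strict)
  rej <- res$report$rejections
  expect_identical(rej$rule[rej$id == "cyclic_allene"], "cumulene_in_ring")
  expect_identical(rej$rule[rej$id == "propadiene"], "cumulene_any")
})

test_that("unknown rule names are refused", {
  expect_error(apply_sanity_filters(list(benzene()), rules = "no_such_rule"),
               class = "decoybench_bad_rule")
  expect_no_error(apply_sanity_filters(list(benzene()),
                                       rules = "cumulene_in_ring"))
})
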