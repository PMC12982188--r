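score_row <- function(pair_id, replica, metric, value, label = NULL) {
  t <- tibble::tibble(pair_id = pair_id, replica = replica, metric = metric,
                      value = value)
  if (!is.null(label)) t$label <- label
  t
}

test_that("ranking follows the metric's declared direction", {
  t <- score_row(c("a", "b", "c"), 1L, "gnina_affinity", c(-8, -6, -7))
  rk <- rank_by_metric(t, "gnina_affinity", 1L)
  expect_identical(rk$pair_id, c("a", "c", "b"))
  expect_identical(rk$value, c(-8, -7, -6))
  expect_identical(rk$rank, 1:3)

  th <- score_row(c("a", "b", "c"), 1L, "cnn_pose_score", c(0.2, 0.9, 0.4))
  expect_identical(rank_by_metric(th, "cnn_pose_score", 1L)$pair_id,
                   c("b", "c", "a"))
})

test_that("ties break by pair id lexicographically", {
  t <- score_row(c("zeta", "beta", "alpha"), 1L, "cnn_pose_score",
                 c(0.2, 0.9, 0.9))
  rk <- rank_by_metric(t, "cnn_pose_score", 1L)
  expect_identical(rk$pair_id, c("alpha", "beta", "zeta"))
})

test_that("missing scores shrink N-prime and are reported, never imputed", {
  t <- dplyr::bind_rows(
    score_row(c("a", "b", "c"), 1L, "mm_gbsa", c(-30, -20, -25)),
    score_row(c("a", "b"), 2L, "mm_gbsa", c(-31, -19))
  )
  rk <- rank_by_metric(t, "mm_gbsa", 2L)
  expect_identical(nrow(rk), 2L)
  expect_identical(completeness_report(rk)$pair_id, "c")
  expect_identical(glance(rk)$n_missing, 1L)
})

test_that("replica aggregation averages or takes the best per direction", {
  t <- dplyr::bind_rows(
    score_row("a", 1L, "gnina_affinity", -7),
    score_row("a", 2L, "gnina_affinity", -5),
    score_row("b", 1L, "gnina_affinity", -6.5),
    score_row("b", 2L, "gnina_affinity", -6.5)
  )
  mean_rk <- aggregate_replicas(t, "gnina_affinity", "mean")
  expect_identical(mean_rk$value[mean_rk$pair_id == "a"], -6)
  best_rk <- aggregate_replicas(t, "gnina_affinity", "best")
  expect_identical(best_rk$value[best_rk$pair_id == "a"], -7)

  th <- dplyr::bind_rows(
    score_row("a", 1L, "cnn_pose_score", 0.3),
    score_row("a", 2L, "cnn_pose_score", 0.9)
  )
  expect_identical(aggregate_replicas(th, "cnn_pose_score", "best")$value, 0.9)
})

test_that("identical replicas make every aggregation equal each replica", {
  base <- score_row(sprintf("p%02d", 1:10), 1L, "rmsd", c(3, 1, 4, 1.5, 9, 2.6,
                                                          5.3, 5.8, 9.7, 0.3))
  t <- dplyr::bind_rows(base, dplyr::mutate(base, replica = 2L),
                        dplyr::mutate(base, replica = 3L))
  single <- rank_by_metric(t, "rmsd", 1L)
  for (mode in c("mean", "best")) {
    agg <- aggregate_replicas(t, "rmsd", mode)
    expect_identical(agg$pair_id, single$pair_id)
    expect_identical(agg$rank, single$rank)
  }
})

test_that("unregistered metrics are refused until declared", {
  t <- score_row("a", 1L, "egb", -12)
  expect_error(rank_by_metric(t, "egb", 1L), class = "decoybench_bad_metric")
  reg <- register_metric(metric_registry(), "egb", "lower", "kcal/mol")
  expect_identical(rank_by_metric(t, "egb", 1L, registry = reg)$rank, 1L)
  expect_error(register_metric(reg, "egb", "lower"),
               class = "decoybench_bad_metric")
  expect_error(validate_scores(dplyr::bind_rows(t, t)),
               class = "decoybench_bad_input")
})

test_that("every ranking is a permutation of 1..N-prime", {
  for (seed in c(2, 17, 31)) {
    scores <- random_score_fixture(seed = seed, n_actives = 5L,
                                   n_decoys = 40L, replicas = 3L)
    # knock out a few values to vary N'
    scores$value[withr::with_seed(seed, sample.int(nrow(scores), 7L))] <- NA
    for (r in 1:3) {
      rk <- rank_by_metric(scores, "gnina_affinity", r)
      expect_identical(sort(rk$rank), seq_len(nrow(rk)))
      expect_false(anyDuplicated(rk$pair_id) > 0L)
    }
    agg <- aggregate_replicas(scores, "gnina_affinity", "mean")
    expect_identical(sort(agg$rank), seq_len(nrow(agg)))
  }
})
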