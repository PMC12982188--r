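# helper: a score table whose per-replica values are fully controlled:
# `values` is a named list pair_id -> numeric vector over replicas
controlled_scores <- function(values, metric = "rmsd") {
  purrr::imap_dfr(values, function(v, id) {
    tibble::tibble(pair_id = id, replica = seq_along(v), metric = metric,
                   value = v)
  })
}

test_that("zero replica variance gives a degenerate rank interval", {
  # four pairs with constant ranks across 4 replicas
  t <- controlled_scores(list(a = rep(1, 4), b = rep(2, 4), c = rep(3, 4),
                              d = rep(4, 4)))
  ci <- rank_confidence(t, "rmsd")
  expect_identical(ci$lower, as.numeric(ci$point))
  expect_identical(ci$upper, as.numeric(ci$point))
  expect_true(all(ci$width == 0))
  expect_identical(ci$point[ci$pair_id == "c"], 3)
})

test_that("t-intervals round outward and clip to the list bounds", {
  # pair 'x' ranks {2,1,1,1}: mean 1.25, sd 0.5, SE 0.25,
  # t(.975,3)=3.1824 -> [0.4544, 2.0456] -> floor/ceil -> clip at 1 -> [1,3]
  t <- controlled_scores(list(
    x = c(1.5, 0.5, 0.5, 0.5),
    y = c(1.0, 2.0, 2.0, 2.0),
    z = c(3.0, 3.0, 3.0, 3.0)
  ))
  ci <- rank_confidence(t, "rmsd")
  x <- ci[ci$pair_id == "x", ]
  expect_identical(x$point, 1.25)
  expect_identical(x$lower, 1)
  expect_identical(x$upper, 3)

  # hand-checked outward rounding away from the boundary:
  # ranks {10,11,12,11}: mean 11, sd 0.8165, SE 0.40825 -> 11 +/- 1.2993
  ranks <- c(10, 11, 12, 11)
  b <- decoybench:::ci_bounds(ranks, "t")
  expect_equal(unname(b["lower"]), 9.7007, tolerance = 1e-4)
  expect_equal(unname(b["upper"]), 12.2993, tolerance = 1e-4)
})

test_that("the min-max envelope is available as the conservative interval", {
  t <- controlled_scores(list(
    x = c(1.5, 0.5, 0.5, 0.5),
    y = c(1.0, 2.0, 2.0, 2.0),
    z = c(3.0, 3.0, 3.0, 3.0)
  ))
  ci <- rank_confidence(t, "rmsd", ci = "range")
  x <- ci[ci$pair_id == "x", ]
  expect_identical(c(x$lower, x$upper), c(1, 2))
})

test_that("pairs with fewer than two replicas get an explicit note", {
  t <- dplyr::bind_rows(
    controlled_scores(list(a = c(1, 1), b = c(2, 2))),
    tibble::tibble(pair_id = "c", replica = 1L, metric = "rmsd", value = 9)
  )
  ci <- rank_confidence(t, "rmsd")
  expect_identical(ci$note[ci$pair_id == "c"], "insufficient_replicas")
  expect_true(is.na(ci$lower[ci$pair_id == "c"]))
  expect_true(all(ci$note[ci$pair_id != "c"] == ""))
})

test_that("identical replicas give a zero-width score band", {
  base <- stats::setNames(as.list(c(2.2, 3.1, 0.4, 5.5, 1.9)),
                          sprintf("p%d", 1:5))
  t <- controlled_scores(lapply(base, rep, times = 4L))
  rc <- score_band(t, "rmsd")
  expect_identical(rc$lower, rc$mean)
  expect_identical(rc$upper, rc$mean)
  expect_identical(rc$mean, unname(sort(unlist(base))))
})

test_that("mean band curves are monotone in the metric's direction", {
  for (seed in c(5, 23)) {
    lower_t <- random_score_fixture(seed = seed)
    rc <- score_band(lower_t, "gnina_affinity")
    expect_true(all(diff(rc$mean) >= 0))   # lower-is-better: ascending

    cfg <- synthetic_score_config(metric = "cnn_pose_score", shift = 0.2,
                                  noise = 0.05, base_mean = 0.5,
                                  base_sd = 0.15, seed = seed)
    higher_t <- generate_synthetic_scores(cfg)
    rc2 <- score_band(higher_t, "cnn_pose_score")
    expect_true(all(diff(rc2$mean) <= 0))  # higher-is-better: descending
  }
})

test_that("band width tracks the planted inter-replica noise", {
  quiet <- random_score_fixture(seed = 9, noise = 0.05)
  loud <- random_score_fixture(seed = 9, noise = 1.0)
  w_quiet <- mean(with(score_band(quiet, "gnina_affinity"), upper - lower))
  w_loud <- mean(with(score_band(loud, "gnina_affinity"), upper - lower))
  expect_gt(w_loud, w_quiet * 3)
})

test_that("replicas of unequal coverage align on the intersection", {
  t <- dplyr::bind_rows(
    controlled_scores(list(a = c(1, 1.1), b = c(2, 2.1), c = c(3, 3.2))),
    tibble::tibble(pair_id = "d", replica = 1L, metric = "rmsd", value = 4)
  )
  rc <- score_band(t, "rmsd")
  expect_identical(nrow(rc), 3L)
  expect_identical(attr(rc, "dropped_pairs"), "d")
})

test_that("mean-of-ranks equals rank-of-means under identical replicas", {
  scores <- random_score_fixture(seed = 4, noise = 0)  # replicas identical
  rc <- score_band(scores, "gnina_affinity")
  act <- curve_actives(rc)
  expect_identical(nrow(act), 3L)
  expect_equal(act$mean_of_ranks, as.numeric(act$rank_of_means))
  expect_true(all(act$lower == act$upper))
  # and the curve marks exactly those positions
  expect_identical(which(rc$is_active), sort(act$rank_of_means))
})

test_that("recovery marks count the binders and a perfect scorer leads the list", {
  scores <- random_score_fixture(seed = 2, shift = 50, noise = 0.1)
  rk <- aggregate_replicas(scores, "gnina_affinity", "mean")
  pos <- recovery_positions(rk, scores)
  expect_identical(pos$rank, 1:3)

  null_scores <- random_score_fixture(seed = 2, shift = 0)
  pos0 <- recovery_positions(aggregate_replicas(null_scores, "gnina_affinity",
                                                "mean"), null_scores)
  expect_identical(nrow(pos0), 3L)

  # no binders -> empty mark set
  all_decoy <- dplyr::mutate(null_scores, label = "decoy")
  expect_identical(nrow(recovery_positions(
    aggregate_replicas(all_decoy, "gnina_affinity", "mean"), all_decoy)), 0L)
})

test_that("violin summaries use linear-interpolation quantiles", {
  # one active whose rank walks 1,2,3,4 over the four replicas
  t <- controlled_scores(list(
    A = c(0.5, 1.5, 2.5, 3.5),
    d1 = rep(1, 4), d2 = rep(2, 4), d3 = rep(3, 4)
  ))
  t$label <- ifelse(t$pair_id == "A", "binder", "decoy")
  s <- rank_distribution_summary(t, "rmsd")
  expect_identical(s$median, 2.5)
  expect_identical(s$q1, 1.75)
  expect_identical(s$q3, 3.25)
  expect_identical(c(s$min, s$max), c(1L, 4L))

  per <- rank_distribution_summary(t, "rmsd", pooling = "per_active")
  expect_identical(per$pair_id, "A")
  expect_identical(per$n, 4L)

  # a single observed rank collapses all summaries onto it
  t1 <- controlled_scores(stats::setNames(as.list(1:7 / 10), sprintf("q%d", 1:7)))
  t1 <- t1[t1$replica == 1L, ]
  t1$label <- ifelse(t1$pair_id == "q7", "binder", "decoy")
  s1 <- rank_distribution_summary(t1, "rmsd")
  expect_true(all(c(s1$median, s1$q1, s1$q3, s1$min, s1$max) == 7))
})

test_that("an order-dominating metric dominates in every summary statistic", {
  t <- dplyr::bind_rows(
    controlled_scores(list(A = c(0.5, 1.5), d1 = rep(1, 2), d2 = rep(2, 2),
                           d3 = rep(3, 2)), metric = "rmsd"),
    controlled_scores(list(A = c(3.5, 2.5), d1 = rep(1, 2), d2 = rep(2, 2),
                           d3 = rep(3, 2)), metric = "mm_gbsa")
  )
  t$label <- ifelse(t$pair_id == "A", "binder", "decoy")
  good <- rank_distribution_summary(t, "rmsd")
  bad <- rank_distribution_summary(t, "mm_gbsa")
  expect_true(all(unlist(good[, c("median", "q1", "q3", "min", "max")]) <=
                    unlist(bad[, c("median", "q1", "q3", "min", "max")])))
})
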