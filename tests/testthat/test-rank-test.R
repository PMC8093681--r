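test_that("within-group pairwise distances enumerate correctly", {
  rad <- manual_rad(rank = c(2L, 5L, 1L), group_key = c("a", "a", NA))
  expect_equal(pairwise_rank_distances(rad), 3)

  rad3 <- manual_rad(rank = c(1L, 4L, 5L, 2L, 3L),
                     group_key = c("a", "a", "a", NA, NA))
  expect_setequal(pairwise_rank_distances(rad3), c(3, 4, 1))
  expect_equal(sort(pairwise_rank_distances(rad3, mode = "adjacent_only")), c(1, 3))

  tied <- manual_rad(rank = c(1L, 1L, 3L), group_key = c("a", "a", NA),
                     frequency = c(0.4, 0.4, 0.2))
  expect_equal(pairwise_rank_distances(tied), 0)

  expect_error(pairwise_rank_distances(manual_rad(1:4)), class = "radlabel_no_pairs")
})

test_that("observed indices match direct arithmetic", {
  rad <- manual_rad(rank = c(1L, 4L, 5L, 2L, 5L, 3L),
                    group_key = c("a", "a", "a", "b", "b", NA),
                    frequency = c(0.4, 0.1, 0.05, 0.3, 0.05, 0.1))
  obs <- observed_statistics(rad)
  expect_equal(obs$mean_rank, mean(c(1, 4, 5, 2, 5)))
  expect_equal(obs$sd_distance, sd(c(3, 4, 1, 3)))
  expect_equal(obs$n_distances, 4L)

  # two-point sample SD and the constant-distance case
  r2 <- manual_rad(rank = c(1L, 2L, 4L, 5L, 7L, 8L),
                   group_key = c("a", "b", "a", "b", "c", "c"))
  # distances: a: 3, b: 3, c: 1
  expect_equal(observed_statistics(r2)$sd_distance, sd(c(3, 3, 1)))
  const <- manual_rad(rank = c(1L, 4L, 2L, 5L, 3L, 6L),
                      group_key = c("a", "a", "b", "b", "c", "c"))
  expect_equal(observed_statistics(const)$sd_distance, 0)

  # relative scale divides ranks by the resolution
  rel <- observed_statistics(rad, rank_scale = "relative", resolution = 10)
  expect_equal(rel$mean_rank, mean(c(1, 4, 5, 2, 5)) / 10)
  expect_equal(rel$sd_distance, sd(c(3, 4, 1, 3)) / 10)

  one <- manual_rad(rank = c(1L, 3L, 2L), group_key = c("a", "a", NA))
  expect_error(observed_statistics(one), class = "radlabel_undefined_sd")
})

test_that("identity randomization preserves everything except the labels", {
  rad <- manual_rad(rank = c(1L, 2L, 2L, 4L, 5L, 6L),
                    group_key = c("a", "a", "b", "b", NA, NA),
                    frequency = c(0.3, 0.2, 0.2, 0.15, 0.1, 0.05))
  perm <- randomize_identities(rad, seed = 99)
  expect_identical(perm$frequency, rad$frequency)
  expect_identical(perm$rank, rad$rank)
  expect_identical(tie_structure(perm), tie_structure(rad))
  expect_identical(sort(perm$group_key, na.last = TRUE),
                   sort(rad$group_key, na.last = TRUE))
  expect_identical(randomize_identities(rad, seed = 99), perm)
})

test_that("a single all-inclusive group is invariant under permutation", {
  rad <- manual_rad(rank = 1:5, group_key = rep("a", 5))
  obs <- observed_statistics(rad)
  for (seed in 1:5) {
    perm <- randomize_identities(rad, seed = seed)
    expect_equal(observed_statistics(perm), obs)
  }
  rt <- randomization_test(rad, n_trials = 50, seed = 1)
  expect_equal(rt$p_sd, 1)
})

test_that("three-species pair-group null has exactly the three enumerable placements", {
  placements <- list(c("a", "a", NA), c("a", NA, "a"), c(NA, "a", "a"))
  ds <- vapply(placements, function(k) {
    pairwise_rank_distances(manual_rad(rank = 1:3, group_key = k))
  }, numeric(1))
  expect_equal(sort(ds), c(1, 1, 2))
})

test_that("exact enumeration matches the brute-force permutation oracle", {
  cases <- list(
    list(rank = c(1L, 2L, 3L, 4L, 5L, 6L), key = c("a", NA, "a", NA, "b", "b")),
    list(rank = c(1L, 2L, 2L, 4L, 5L, 6L, 7L), key = c("a", "a", "b", "b", "b", NA, NA)),
    list(rank = c(1L, 2L, 3L, 3L, 5L, 6L), key = c("a", "a", "a", NA, "b", "b"))
  )
  for (cs in cases) {
    rad <- manual_rad(rank = cs$rank, group_key = cs$key)
    for (mode in c("all_pairs", "adjacent_only")) {
      ex <- exact_rank_test(rad, mode = mode)
      bf <- brute_force_rank_test(cs$rank, cs$key, mode = mode)
      expect_equal(ex$observed_sd, bf$observed_sd)
      expect_equal(ex$observed_mean_rank, bf$observed_mean)
      expect_equal(ex$p_sd, bf$p_sd, tolerance = 1e-12)
      expect_equal(ex$side, bf$side)
      expect_equal(ex$p_rank, bf$p_rank, tolerance = 1e-12)
      expect_equal(ex$null_mean_mean, bf$grand_mean, tolerance = 1e-12)
    }
  }
})

test_that("Monte Carlo probabilities converge on the exact values", {
  rad <- manual_rad(rank = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
                    group_key = c("a", "a", NA, "b", "b", "b", NA, NA))
  ex <- exact_rank_test(rad)
  mc <- randomization_test(rad, n_trials = 20000, seed = 3)
  se_sd <- sqrt(ex$p_sd * (1 - ex$p_sd) / mc$n_trials)
  expect_lt(abs(mc$p_sd - ex$p_sd), 3 * se_sd + 1e-12)
  se_rank <- sqrt(ex$p_rank * (1 - ex$p_rank) / max(mc$n_same_side, 1))
  expect_lt(abs(mc$p_rank - ex$p_rank), 3 * se_rank + 1e-12)
  expect_equal(mc$side, ex$side)
})

test_that("rank test bookkeeping: joint product, determinism, extremes", {
  rad <- manual_rad(rank = 1:8, group_key = c("a", "a", NA, "b", "b", NA, NA, NA))
  rt <- randomization_test(rad, n_trials = 2000, seed = 11)
  expect_equal(rt$joint_p, rt$p_sd * rt$p_rank, tolerance = 1e-15)
  expect_true(rt$p_sd >= 0 && rt$p_sd <= 1)
  expect_true(rt$p_rank >= 0 && rt$p_rank <= 1)
  rt2 <- randomization_test(rad, n_trials = 2000, seed = 11)
  expect_identical(glance(rt), glance(rt2))

  # an observed SD below every achievable null value gives p_sd = 0
  tight <- manual_rad(rank = c(1L, 1L, 3L, 4L, 5L, 6L),
                      frequency = c(0.3, 0.3, 0.2, 0.1, 0.06, 0.04),
                      group_key = c("a", "a", "b", "b", NA, NA))
  # observed distances {0, 1}; most placements spread much wider
  rt3 <- randomization_test(tight, n_trials = 500, seed = 2)
  expect_lt(rt3$p_sd, 0.5)
})

test_that("p_sd is approximately uniform under the null", {
  tb <- generate_null_table(12, c(2, 2, 3), tie_rate = 0, integer_counts = FALSE,
                            seed = 77)
  rad <- rank_with_ties(tb)
  p_vals <- vapply(seq_len(400), function(i) {
    shuffled <- randomize_identities(rad, seed = 1000 + i)
    randomization_test(shuffled, n_trials = 199, seed = 5000 + i,
                       keep_null = FALSE)$p_sd
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_gt(mean(p_vals), 0.4)
  expect_lt(mean(p_vals), 0.6)
})

test_that("significance marks follow the 5/10/15 percent bands", {
  expect_equal(significance_mark(c(0.04, 0.05, 0.07, 0.12, 0.15, 0.2, 0.5)),
               c("+++", "+++", "++", "+", "+", "", ""))
  expect_error(significance_mark(1.2), class = "radlabel_parameter_error")
})

test_that("model communities show the quasi-exclusion signal in the rank test", {
  p_sds <- c()
  below <- c()
  for (seed in 1:10) {
    spec <- reference_community("saturating", n = 30,
                                perturbation = "jitter_half_interval", seed = seed)
    rad <- adjacency_groups(build_rad(solve_equilibrium(spec)))
    rt <- tryCatch(
      randomization_test(rad, n_trials = 1000, seed = seed,
                         mode = "adjacent_only", rank_scale = "relative",
                         keep_null = FALSE),
      error = function(e) NULL
    )
    if (is.null(rt)) next
    p_sds <- c(p_sds, rt$p_sd)
    below <- c(below, rt$observed_sd < rt$null_sd_mean)
  }
  expect_gte(length(p_sds), 5)
  expect_lt(median(p_sds), 0.5)
  expect_gt(mean(below), 0.5)
})
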