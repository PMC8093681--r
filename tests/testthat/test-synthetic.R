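test_that("null tables honour the requested group layout and are reproducible", {
  tb <- generate_null_table(39, c(2, 2, 2, 2, 2, 3), seed = 1)
  expect_equal(nrow(tb), 39)
  expect_true(all(tb$abundance > 0))
  rad <- rank_with_ties(tb)
  expect_equal(sort(as.integer(table(rad$group_key[!rad$singleton]))),
               c(2L, 2L, 2L, 2L, 2L, 3L))
  expect_identical(tb, generate_null_table(39, c(2, 2, 2, 2, 2, 3), seed = 1))
  expect_false(identical(tb, generate_null_table(39, c(2, 2, 2, 2, 2, 3), seed = 2)))
  expect_error(generate_null_table(4, c(3, 3)), class = "radlabel_spec_error")
  expect_error(generate_null_table(6, c(1, 2)), class = "radlabel_spec_error")
})

test_that("continuous abundances without tying are tie-free", {
  tb <- generate_null_table(30, c(2, 2), tie_rate = 0, integer_counts = FALSE, seed = 3)
  expect_equal(anyDuplicated(tb$abundance), 0L)
  # positive tie rate produces tied ranks
  tb2 <- generate_null_table(30, c(2, 2), tie_rate = 0.5, integer_counts = FALSE, seed = 3)
  expect_gt(sum(duplicated(tb2$abundance)), 0)
})

test_that("log-series abundances are positive integers with a hollow curve", {
  tb <- generate_null_table(50, integer_counts = TRUE,
                            abundance_model = "logseries", seed = 9)
  expect_true(all(tb$abundance >= 1))
  expect_true(all(tb$abundance == round(tb$abundance)))
  expect_gt(sum(tb$abundance == min(tb$abundance)), sum(tb$abundance == max(tb$abundance)))
})

test_that("structured tables carry the model's abundances and adjacency groups", {
  tb <- generate_structured_table(spec_from_fecundities(c(2, 5, 6), 1, 1), scale = 1000)
  expect_equal(tb$abundance, c(833, 167))
  expect_equal(tb$genus[1], tb$genus[2])  # grid neighbours share a group

  expect_error(generate_structured_table(spec_from_fecundities(c(2, 3, 6), 1, 1),
                                         grouping = "none"),
               NA)
  singles <- generate_structured_table(spec_from_fecundities(c(2, 3, 6), 1, 1),
                                       grouping = "none")
  expect_error(randomization_test(rank_with_ties(singles), n_trials = 10),
               class = "radlabel_no_pairs")

  expect_error(generate_structured_table(spec_from_fecundities(2, 1, 1)),
               class = "radlabel_infeasible")
})

test_that("perturbed ensembles respect bounds and stay sorted", {
  spec <- reference_community("saturating", n = 20)
  ens <- generate_perturbed_ensemble(spec, "jitter_half_interval",
                                     n_replicates = 10, seed = 4)
  expect_length(ens, 10)
  h <- spec$trade_off$x_hat / spec$n
  base <- make_positions(spec$n, spec$trade_off$x_hat)
  for (s in ens) {
    expect_true(all(abs(s$positions - base) <= h / 2 + 1e-9))
    expect_true(all(diff(s$positions) > 0))
  }
  ens2 <- generate_perturbed_ensemble(spec, "uniform_random", n_replicates = 5, seed = 4)
  for (s in ens2) {
    expect_true(all(s$positions >= 0 & s$positions <= spec$trade_off$x_hat))
    expect_true(all(diff(s$positions) > 0))
  }
  expect_identical(
    lapply(ens, `[[`, "positions"),
    lapply(generate_perturbed_ensemble(spec, "jitter_half_interval", 10, seed = 4),
           `[[`, "positions")
  )
})

test_that("small position jitter makes abundance more even on average", {
  spec <- reference_community("saturating", n = 30)
  base_simpson <- simpson_index(build_rad(solve_equilibrium(spec)))
  ens <- generate_perturbed_ensemble(spec, "jitter_half_interval",
                                     n_replicates = 20, seed = 6)
  jittered <- vapply(ens, function(s) simpson_index(build_rad(solve_equilibrium(s))),
                     numeric(1))
  expect_gte(mean(jittered), base_simpson)
})

test_that("structured tables carry a detectable quasi-exclusion signal", {
  # power against the model-generated alternative must exceed the nominal
  # type-I rate of the test under the null
  p_structured <- c()
  below <- c()
  for (seed in 1:15) {
    spec <- reference_community("saturating", n = 30,
                                perturbation = "jitter_half_interval", seed = seed)
    tb <- generate_structured_table(spec)
    rt <- tryCatch(
      randomization_test(rank_with_ties(tb), n_trials = 400, seed = seed,
                         keep_null = FALSE),
      error = function(e) NULL  # some layouts have a lone adjacent pair
    )
    if (is.null(rt)) next
    p_structured <- c(p_structured, rt$p_sd)
    below <- c(below, rt$observed_sd < rt$null_sd_mean)
  }
  expect_gte(length(p_structured), 8)
  expect_gt(mean(below), 0.5)
  expect_gt(mean(p_structured <= 0.05), 0.2)
})
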