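manual_eq <- function(p, moq = 0.1) {
  # equilibrium container with prescribed frequencies, for labeling tests
  spec <- spec_from_fecundities(seq_along(p) + 1, m = moq, q = 1)
  structure(list(spec = spec, frequencies = p, survivors = p > 0,
                 empty_fraction = 1 - sum(p), converged = TRUE),
            class = "equilibrium_community")
}

test_that("peak labeling follows the grid-neighbour rule", {
  expect_equal(label_peaks(manual_eq(c(0.3, 0.1, 0.2))), c(TRUE, FALSE, TRUE))
  expect_equal(label_peaks(manual_eq(c(0.5, 0.1, 0))), c(TRUE, FALSE, NA))
  # monotone decreasing, all positive: only the top competitor is a peak
  expect_equal(label_peaks(manual_eq(c(0.4, 0.3, 0.2, 0.05))),
               c(TRUE, FALSE, FALSE, FALSE))
  # extinct interior neighbour counts as zero frequency
  expect_equal(label_peaks(manual_eq(c(0.3, 0, 0.2, 0.1))),
               c(TRUE, NA, TRUE, FALSE))
  expect_equal(label_peaks(manual_eq(0.7)), TRUE)
})

test_that("every included species is exactly one of peak or non-peak", {
  eq <- solve_equilibrium(reference_community("sigmoid", n = 40))
  peaks <- label_peaks(eq)
  expect_true(all(is.na(peaks[!eq$survivors])))
  expect_true(all(!is.na(peaks[eq$survivors])))
})

test_that("RAD construction filters, renormalizes, and ranks with min ties", {
  rad <- build_rad(manual_eq(c(0.5, 0.1, 0)))
  expect_equal(nrow(rad), 2)
  expect_equal(rad$frequency, c(5 / 6, 1 / 6))
  expect_equal(rad$rank, c(1L, 2L))
  expect_equal(rad$peak, c(TRUE, FALSE))
  expect_equal(sum(rad$frequency), 1, tolerance = 1e-12)

  # sub-threshold species vanish entirely
  rad1 <- build_rad(manual_eq(c(0.5, 5e-8)))
  expect_equal(nrow(rad1), 1)
  expect_equal(rad1$frequency, 1)

  # exact ties share rank 1
  rad3 <- build_rad(manual_eq(c(0.2, 0.2, 0.2)))
  expect_equal(rad3$rank, c(1L, 1L, 1L))
  expect_equal(tie_structure(rad3)$n_species, 3L)

  expect_error(build_rad(manual_eq(c(1e-9, 1e-8))), class = "radlabel_empty_rad")
})

test_that("Simpson's index behaves on closed-form cases", {
  expect_equal(simpson_index(build_rad(manual_eq(0.4))), 0)
  expect_equal(simpson_index(build_rad(manual_eq(rep(0.15, 5)))), 1 - 1 / 5)
  expect_equal(simpson_index(build_rad(manual_eq(c(0.5, 0.1, 0)))), 1 - 26 / 36)
  # bounded by 1 - 1/S for a model community
  rad <- build_rad(solve_equilibrium(reference_community("saturating", n = 30)))
  expect_gte(simpson_index(rad), 0)
  expect_lte(simpson_index(rad), 1 - 1 / nrow(rad))
})

test_that("SAD histograms rescale to 11 classes and conserve species counts", {
  two <- sad_histograms(build_rad(manual_eq(c(0.5, 0.2))))
  expect_equal(two$linear$count[c(1, 11)], c(1L, 1L))
  expect_equal(sum(two$linear$count), 2L)

  # equal spacing on the raw scale: classes 1, 6, 11
  three <- sad_histograms(build_rad(manual_eq(c(0.1, 0.2, 0.3))))
  expect_equal(which(three$linear$count == 1L), c(1L, 6L, 11L))
  # log2 view of a geometric series is equally spaced instead
  geo <- sad_histograms(build_rad(manual_eq(c(0.4, 0.2, 0.1))))
  expect_equal(which(geo$log2$count == 1L), c(1L, 6L, 11L))

  rad <- build_rad(solve_equilibrium(reference_community("saturating", n = 30)))
  h <- sad_histograms(rad)
  expect_equal(sum(h$linear$count), nrow(rad))
  expect_equal(sum(h$log2$count), nrow(rad))
  expect_error(sad_histograms(build_rad(manual_eq(0.5))),
               class = "radlabel_degenerate_histogram")
})

test_that("neighbour-survival fraction counts adjacency on the grid", {
  expect_equal(neighbor_survival_fraction(manual_eq(c(0.5, 0.1, 0))),
               c(numerator = 2, denominator = 2))
  expect_equal(neighbor_survival_fraction(manual_eq(c(0.5, 0, 1 / 6))),
               c(numerator = 0, denominator = 2))
  expect_equal(neighbor_survival_fraction(manual_eq(c(0, 0, 0))),
               c(numerator = 0, denominator = 0))
})

test_that("peak species cluster at high ranks in saturating model communities", {
  ranks_by_type <- function(seed) {
    spec <- reference_community("saturating", n = 30,
                                perturbation = "jitter_half_interval", seed = seed)
    rad <- build_rad(solve_equilibrium(spec))
    c(mean(rad$rank[rad$peak]), mean(rad$rank[!rad$peak]))
  }
  res <- vapply(1:12, ranks_by_type, numeric(2))
  expect_true(mean(res[1, ] < res[2, ]) > 0.5)
  expect_lt(mean(res[1, ]), mean(res[2, ]))
})

test_that("adjacency grouping joins exactly the runs of surviving neighbours", {
  eq <- manual_eq(c(0.3, 0.2, 0, 0.1, 0.05, 0.04, 0, 0.02))
  rad <- adjacency_groups(build_rad(eq))
  tb <- tibble::as_tibble(rad)[order(tibble::as_tibble(rad)$grid_index), ]
  expect_equal(tb$group_key, c("adj1", "adj1", "adj2", "adj2", "adj2", "s8"))
  expect_error(adjacency_groups(manual_rad(1:3)), class = "radlabel_parameter_error")
})
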