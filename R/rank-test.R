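#' @keywords internal
#' Resolve the grouping of a RAD into permutation-ready indices.
#'
#' Species whose group_key is NA or shared by no other ranked species are
#' singletons: they keep their slots in the permutation universe but
#' contribute to neither index.
group_layout <- function(rad, groups = NULL) {
  tb <- tibble::as_tibble(rad)
  if (!is.null(groups)) {
    stopifnot(all(c("species_id", "group_key") %in% names(groups)))
    tb$group_key <- groups$group_key[match(tb$species_id, groups$species_id)]
  }
  key <- tb$group_key
  sizes <- table(key[!is.na(key)])
  multi <- names(sizes)[sizes >= 2L]
  member_pos <- lapply(multi, function(g) which(!is.na(key) & key == g))
  list(
    ranks = as.numeric(tb$rank),
    S = nrow(tb),
    group_keys = multi,
    member_pos = member_pos,
    sizes = lengths(member_pos)
  )
}

# distance statistics for one arrangement of member ranks (list by group)
pooled_distances <- function(rank_sets, mode) {
  unlist(lapply(rank_sets, function(rv) {
    if (length(rv) < 2L) return(numeric(0))
    if (mode == "all_pairs") {
      d <- abs(outer(rv, rv, "-"))
      d[upper.tri(d)]
    } else {
      diff(sort(rv))
    }
  }), use.names = FALSE)
}

#' Within-group pairwise rank distances
#'
#' For every similarity group with at least two ranked members, emits the
#' absolute rank distances between member pairs: all unordered pairs
#' (`mode = "all_pairs"`, as in the empirical analyses) or only rank-adjacent
#' members within each group (`mode = "adjacent_only"`, the bias check for
#' groups of three or more, where all-pairs measurement can overestimate the
#' SD). Tied ranks give distance 0.
#'
#' @param rad A `rad_community` (its `group_key` column defines groups).
#' @param groups Optional data frame (`species_id`, `group_key`) overriding
#'   the RAD's grouping.
#' @param mode `"all_pairs"` or `"adjacent_only"`.
#' @return Numeric vector of pooled distances.
#' @examples
#' rad <- manual_rad(rank = c(1, 4, 5), group_key = c("a", "a", "a"))
#' pairwise_rank_distances(rad)                         # 3 4 1
#' pairwise_rank_distances(rad, mode = "adjacent_only") # 3 1
#' @export
pairwise_rank_distances <- function(rad, groups = NULL,
                                    mode = c("all_pairs", "adjacent_only")) {
  mode <- rlang::arg_match(mode)
  lay <- group_layout(rad, groups)
  if (length(lay$member_pos) == 0L) {
    rlang::abort("No group has two or more ranked members: no pairs to measure.",
                 class = "radlabel_no_pairs")
  }
  pooled_distances(lapply(lay$member_pos, function(ix) lay$ranks[ix]), mode)
}

#' Observed indices of a labeled RAD
#'
#' The two indices of the quasi-exclusion prediction: the sample standard
#' deviation (divisor `N - 1`) of all within-group pairwise rank distances,
#' and the mean rank of all species belonging to groups of size two or more.
#' With `rank_scale = "relative"` ranks are divided by the stated resolution
#' (the model's species count) before both computations, yielding the
#' resolution-relative indices plotted for model communities.
#'
#' @inheritParams pairwise_rank_distances
#' @param rank_scale `"absolute"` or `"relative"`.
#' @param resolution Species resolution for the relative scale; defaults to
#'   the RAD's `resolution` attribute, falling back to the number of ranked
#'   species.
#' @return A one-row tibble: `sd_distance`, `mean_rank`, `n_distances`,
#'   `n_grouped`.
#' @export
observed_statistics <- function(rad, groups = NULL,
                                rank_scale = c("absolute", "relative"),
                                resolution = NULL,
                                mode = c("all_pairs", "adjacent_only")) {
  rank_scale <- rlang::arg_match(rank_scale)
  mode <- rlang::arg_match(mode)
  lay <- group_layout(rad, groups)
  if (length(lay$member_pos) == 0L) {
    rlang::abort("No group has two or more ranked members.", class = "radlabel_no_pairs")
  }
  r <- scale_ranks(lay$ranks, rank_scale, resolution, rad)
  sets <- lapply(lay$member_pos, function(ix) r[ix])
  d <- pooled_distances(sets, mode)
  if (length(d) < 2L) {
    rlang::abort("Fewer than two distances: the SD is undefined.",
                 class = "radlabel_undefined_sd")
  }
  tibble::tibble(
    sd_distance = stats::sd(d),
    mean_rank = mean(unlist(sets)),
    n_distances = length(d),
    n_grouped = sum(lay$sizes)
  )
}

scale_ranks <- function(ranks, rank_scale, resolution, rad) {
  if (rank_scale == "absolute") return(ranks)
  if (is.null(resolution)) resolution <- attr(rad, "resolution")
  if (is.null(resolution) || is.na(resolution)) resolution <- length(ranks)
  ranks / resolution
}

#' Permute species identities on a RAD
#'
#' The null model: abundances, ranks (including ties), and the multiset of
#' group labels are all preserved; only which species carries which label
#' changes, by a uniform random permutation of the label column across the
#' ranked species.
#'
#' @param rad A `rad_community`.
#' @param groups Optional override grouping, as in
#'   [pairwise_rank_distances()].
#' @param seed Integer seed.
#' @return The RAD with its `group_key` column permuted.
#' @export
randomize_identities <- function(rad, groups = NULL, seed = 20210316) {
  tb <- rad
  if (!is.null(groups)) {
    tb$group_key <- groups$group_key[match(tb$species_id, groups$species_id)]
  }
  withr::local_seed(seed)
  tb$group_key <- tb$group_key[sample.int(nrow(tb))]
  tb
}

#' Randomization test of the labeled-RAD indices
#'
#' Shuffles species identities uniformly at random across the RAD's rank
#' positions `n_trials` times, recomputing both indices each time, and
#' reports:
#'
#' * `p_sd`: the fraction of trials whose null rank-distance SD is less than
#'   or equal to the observed SD (small values mean the observed within-group
#'   distances are unusually regular);
#' * `p_rank`: a conditional probability for the mean rank of grouped
#'   species. With `M` the expected within-trial mean rank under
#'   randomization (in closed form the mean of all ranked species' scaled
#'   ranks, since every grouped slot is a uniform draw from the rank
#'   multiset), only trials on the same side of `M` as the observation are
#'   retained, and `p_rank` is the fraction of those at least as extreme as
#'   the observed mean (the analogue of a two-sided test for an asymmetric
#'   discrete null); trials whose mean rank falls exactly on `M` join
#'   neither side;
#' * `joint_p = p_sd * p_rank`, the joint probability of the two criteria.
#'
#' A `p_sd` of 0 is reported as 0; its resolution is `1/n_trials` (no
#' pseudo-count is added). If no trial falls on the observed side of `M`,
#' `p_rank` is reported as `1/(n_trials + 1)` and the result is flagged
#' `degenerate_side`.
#'
#' @inheritParams observed_statistics
#' @param n_trials Number of randomization trials (5,000 is the customary
#'   model-community default; 100,000 for empirical tables).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results.
#' @param p_rank_denominator `"same_side"` (default) conditions on trials on
#'   the observed side of the grand mean; `"all"` divides by all trials.
#' @param keep_null Keep the per-trial null index vectors on the result
#'   (needed by [autoplot.rank_test_result()]).
#' @return A `rank_test_result` object; see [glance.rank_test_result()].
#' @examples
#' rad <- manual_rad(rank = 1:6, group_key = c("a", NA, "a", NA, "b", "b"))
#' rt <- randomization_test(rad, n_trials = 1000, seed = 1)
#' rt$joint_p
#' @export
randomization_test <- function(rad, groups = NULL, n_trials = 5000, seed = 20210316,
                               rank_scale = c("absolute", "relative"),
                               mode = c("all_pairs", "adjacent_only"),
                               resolution = NULL,
                               p_rank_denominator = c("same_side", "all"),
                               keep_null = TRUE) {
  rank_scale <- rlang::arg_match(rank_scale)
  mode <- rlang::arg_match(mode)
  p_rank_denominator <- rlang::arg_match(p_rank_denominator)
  if (n_trials < 1) rlang::abort("`n_trials` must be >= 1.", class = "radlabel_parameter_error")

  lay <- group_layout(rad, groups)
  if (length(lay$member_pos) == 0L) {
    rlang::abort("No group has two or more ranked members.", class = "radlabel_no_pairs")
  }
  r <- scale_ranks(lay$ranks, rank_scale, resolution, rad)
  obs <- observed_statistics(rad, groups, rank_scale = rank_scale,
                             resolution = resolution, mode = mode)

  member_pos <- unlist(lay$member_pos)
  K <- length(member_pos)
  group_cols <- split(seq_len(K), rep(seq_along(lay$member_pos), lay$sizes))

  withr::local_seed(seed)
  M <- matrix(0, nrow = n_trials, ncol = K)
  S <- lay$S
  for (t in seq_len(n_trials)) {
    M[t, ] <- r[sample.int(S)[member_pos]]
  }
  null_stats <- trial_statistics(M, group_cols, mode)

  summarize_rank_test(
    obs_sd = obs$sd_distance, obs_mean = obs$mean_rank,
    null_sd = null_stats$sd, null_mean = null_stats$mean,
    weights = NULL, n_trials = n_trials, seed = seed,
    rank_scale = rank_scale, mode = mode,
    p_rank_denominator = p_rank_denominator,
    n_species = lay$S, group_sizes = lay$sizes,
    exact = FALSE, keep_null = keep_null,
    n_distances = obs$n_distances, grand_mean = mean(r)
  )
}

# per-trial SD of pooled distances and mean member rank, rows = trials
trial_statistics <- function(M, group_cols, mode) {
  if (mode == "all_pairs") {
    pa <- integer(0); pb <- integer(0)
    for (cols in group_cols) {
      if (length(cols) >= 2L) {
        cmb <- utils::combn(cols, 2L)
        pa <- c(pa, cmb[1, ]); pb <- c(pb, cmb[2, ])
      }
    }
    D <- abs(M[, pa, drop = FALSE] - M[, pb, drop = FALSE])
  } else {
    parts <- lapply(group_cols, function(cols) {
      if (length(cols) < 2L) return(NULL)
      sub <- M[, cols, drop = FALSE]
      if (length(cols) == 2L) {
        abs(sub[, 1] - sub[, 2, drop = FALSE])
      } else {
        srt <- t(apply(sub, 1L, sort))
        srt[, -1, drop = FALSE] - srt[, -ncol(srt), drop = FALSE]
      }
    })
    D <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  }
  P <- ncol(D)
  rs <- rowSums(D)
  sd_vec <- if (P >= 2L) sqrt(pmax(rowSums(D^2) - rs^2 / P, 0) / (P - 1)) else rep(NA_real_, nrow(D))
  list(sd = sd_vec, mean = rowMeans(M))
}

summarize_rank_test <- function(obs_sd, obs_mean, null_sd, null_mean, weights,
                                n_trials, seed, rank_scale, mode,
                                p_rank_denominator, n_species, group_sizes,
                                exact, keep_null, n_distances, grand_mean) {
  if (is.null(weights)) weights <- rep(1 / length(null_sd), length(null_sd))
  p_sd <- sum(weights[null_sd <= obs_sd + 1e-12])
  # grand_mean is the closed-form expectation of the within-trial mean rank:
  # each grouped slot is a uniform draw from the rank multiset, so the
  # expectation is the mean of all ranked species' (scaled) ranks. Using it
  # (rather than the trial average) makes the side assignment deterministic:
  # a trial whose mean rank sits exactly on the baseline joins neither side.
  eps <- 1e-9 * max(1, abs(grand_mean))
  side <- if (obs_mean < grand_mean) "below" else "above"
  same_side <- if (side == "below") null_mean < grand_mean - eps
               else null_mean > grand_mean + eps
  extreme <- if (side == "below") null_mean <= obs_mean + 1e-12 else null_mean >= obs_mean - 1e-12
  degenerate <- sum(weights[same_side]) == 0
  denom_w <- if (p_rank_denominator == "same_side") sum(weights[same_side]) else 1
  p_rank <- if (degenerate) 1 / (n_trials + 1) else sum(weights[same_side & extreme]) / denom_w

  structure(
    list(
      observed_sd = obs_sd,
      observed_mean_rank = obs_mean,
      n_trials = n_trials,
      seed = seed,
      p_sd = p_sd,
      p_rank = p_rank,
      side = side,
      joint_p = p_sd * p_rank,
      null_sd_mean = sum(weights * null_sd),
      null_sd_sd = weighted_sd(null_sd, weights),
      null_mean_mean = grand_mean,
      null_mean_empirical = sum(weights * null_mean),
      null_mean_sd = weighted_sd(null_mean, weights),
      n_same_side = if (exact) sum(weights[same_side]) * n_trials else sum(same_side),
      degenerate_side = degenerate,
      rank_scale = rank_scale,
      mode = mode,
      p_rank_denominator = p_rank_denominator,
      n_species = n_species,
      group_sizes = as.integer(group_sizes),
      n_distances = n_distances,
      exact = exact,
      null_sd = if (keep_null) null_sd else NULL,
      null_mean = if (keep_null) null_mean else NULL,
      null_weights = if (keep_null && exact) weights else NULL
    ),
    class = "rank_test_result"
  )
}

# population-style weighted SD of the null summaries
weighted_sd <- function(x, w) {
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

#' Exact rank test by exhaustive enumeration
#'
#' For small communities the permutation null can be enumerated instead of
#' sampled: every distinguishable placement of the multi-member group labels
#' across the rank positions is visited once (singleton labels are
#' interchangeable and need no enumeration), and the probabilities are exact.
#' Feasible up to a few thousand placements — e.g. any community with at most
#' 8 species and two multi-member groups.
#'
#' @inheritParams randomization_test
#' @return A `rank_test_result` with `exact = TRUE`; `n_trials` is the number
#'   of distinguishable placements.
#' @export
exact_rank_test <- function(rad, groups = NULL,
                            rank_scale = c("absolute", "relative"),
                            mode = c("all_pairs", "adjacent_only"),
                            resolution = NULL,
                            p_rank_denominator = c("same_side", "all"),
                            keep_null = TRUE) {
  rank_scale <- rlang::arg_match(rank_scale)
  mode <- rlang::arg_match(mode)
  p_rank_denominator <- rlang::arg_match(p_rank_denominator)
  lay <- group_layout(rad, groups)
  if (length(lay$member_pos) == 0L) {
    rlang::abort("No group has two or more ranked members.", class = "radlabel_no_pairs")
  }
  r <- scale_ranks(lay$ranks, rank_scale, resolution, rad)
  obs <- observed_statistics(rad, groups, rank_scale = rank_scale,
                             resolution = resolution, mode = mode)

  placements <- enumerate_placements(lay$S, lay$sizes)
  stats <- vapply(placements, function(sets) {
    rank_sets <- lapply(sets, function(ix) r[ix])
    d <- pooled_distances(rank_sets, mode)
    c(sd = stats::sd(d), mean = mean(unlist(rank_sets)))
  }, numeric(2))

  n_pl <- length(placements)
  summarize_rank_test(
    obs_sd = obs$sd_distance, obs_mean = obs$mean_rank,
    null_sd = stats["sd", ], null_mean = stats["mean", ],
    weights = rep(1 / n_pl, n_pl), n_trials = n_pl, seed = NA_integer_,
    rank_scale = rank_scale, mode = mode,
    p_rank_denominator = p_rank_denominator,
    n_species = lay$S, group_sizes = lay$sizes,
    exact = TRUE, keep_null = keep_null,
    n_distances = obs$n_distances, grand_mean = mean(r)
  )
}

# all ordered assignments of disjoint position sets of the given sizes
enumerate_placements <- function(S, sizes) {
  res <- list()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes)) {
      res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    k <- sizes[length(acc) + 1L]
    picks <- utils::combn(remaining, k, simplify = FALSE)
    for (pk in picks) recurse(setdiff(remaining, pk), c(acc, list(pk)))
  }
  recurse(seq_len(S), list())
  res
}

#' Significance mark for a randomization probability
#'
#' `"+++"` for `p <= 0.05`, `"++"` for `p <= 0.10`, `"+"` for `p <= 0.15`,
#' empty string otherwise.
#'
#' @param p Probability in `[0, 1]` (vectorised).
#' @return Character vector of marks.
#' @export
significance_mark <- function(p) {
  if (any(p < 0 | p > 1)) {
    rlang::abort("`p` must lie in [0, 1].", class = "radlabel_parameter_error")
  }
  dplyr::case_when(
    p <= 0.05 ~ "+++",
    p <= 0.10 ~ "++",
    p <= 0.15 ~ "+",
    .default = ""
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat("<rank_test_result>", if (x$exact) "(exact enumeration)" else "(Monte Carlo)", "\n")
  cat("  observed SD of rank distances:", signif(x$observed_sd, 5),
      " null:", signif(x$null_sd_mean, 5), "+/-", signif(x$null_sd_sd, 5), "\n")
  cat("  observed mean rank:", signif(x$observed_mean_rank, 5),
      " null:", signif(x$null_mean_mean, 5), "+/-", signif(x$null_mean_sd, 5),
      " side:", x$side, "\n")
  cat("  p_sd:", x$p_sd, significance_mark(x$p_sd),
      "  p_rank:", x$p_rank, significance_mark(x$p_rank),
      "  joint:", x$joint_p, "\n")
  if (x$degenerate_side) cat("  [degenerate side: no same-side trials]\n")
  invisible(x)
}

#' One-row summary of a rank test
#'
#' @param x A `rank_test_result`.
#' @param ... Unused.
#' @return A one-row tibble with the observed indices, null summaries,
#'   probabilities, significance marks, and bookkeeping columns.
#' @export
glance.rank_test_result <- function(x, ...) {
  tibble::tibble(
    observed_sd = x$observed_sd,
    observed_mean_rank = x$observed_mean_rank,
    null_sd_mean = x$null_sd_mean,
    null_sd_sd = x$null_sd_sd,
    null_mean_mean = x$null_mean_mean,
    null_mean_sd = x$null_mean_sd,
    p_sd = x$p_sd,
    p_rank = x$p_rank,
    joint_p = x$joint_p,
    side = x$side,
    mark_sd = significance_mark(x$p_sd),
    mark_rank = significance_mark(x$p_rank),
    n_trials = x$n_trials,
    n_species = x$n_species,
    n_distances = x$n_distances,
    degenerate_side = x$degenerate_side,
    exact = x$exact
  )
}

#' Tidy the null distributions of a rank test
#'
#' @param x A `rank_test_result` computed with `keep_null = TRUE`.
#' @param ... Unused.
#' @return A tibble with one row per trial (or per distinguishable placement
#'   for exact tests): `trial`, `null_sd`, `null_mean_rank`, `weight`.
#' @export
tidy.rank_test_result <- function(x, ...) {
  if (is.null(x$null_sd)) {
    rlang::abort("Null vectors were not kept; rerun with keep_null = TRUE.",
                 class = "radlabel_parameter_error")
  }
  tibble::tibble(
    trial = seq_along(x$null_sd),
    null_sd = x$null_sd,
    null_mean_rank = x$null_mean,
    weight = if (is.null(x$null_weights)) 1 / length(x$null_sd) else x$null_weights
  )
}

#' Construct a RAD by hand
#'
#' Builds a `rad_community` directly from ranks (and optionally frequencies
#' and groups), for worked examples, tests, and ad hoc analyses of
#' pre-ranked data.
#'
#' @param rank Integer ranks (ties allowed, competition style).
#' @param group_key Group labels (`NA` = singleton).
#' @param frequency Normalized frequencies; defaults to a geometric series
#'   consistent with the rank order.
#' @param species_id Species identifiers.
#' @param resolution Optional resolution attribute.
#' @return A `rad_community`.
#' @export
manual_rad <- function(rank, group_key = NA_character_, frequency = NULL,
                       species_id = NULL, resolution = NA_integer_) {
  S <- length(rank)
  if (is.null(species_id)) species_id <- paste0("sp", formatC(seq_len(S), width = 3, flag = "0"))
  if (is.null(frequency)) {
    w <- 0.5^(rank - min(rank))
    frequency <- w / sum(w)
  }
  group_key <- rep_len(as.character(group_key), S)
  new_rad(species_id = species_id, frequency = frequency, rank = rank,
          peak = NA, group_key = group_key, grid_index = NA_integer_,
          resolution = resolution, threshold = NA_real_)
}
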