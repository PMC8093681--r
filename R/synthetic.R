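#' Generate a null community table
#'
#' Draws a grouped abundance table in which group membership carries no
#' information about abundance — the null hypothesis of the randomization
#' test. Abundances come from a lognormal (default, meanlog 3, sdlog 1.2,
#' a realistic hollow-curve community) or a log-series model, are optionally
#' tied between adjacent-abundance species at rate `tie_rate`, and are
#' rounded to integer counts (rounding itself creates natural ties, as in
#' published tables). Group labels (genus x guild) are then assigned
#' uniformly at random across species.
#'
#' @param S Species count.
#' @param group_sizes Integer vector of multi-group sizes (e.g.
#'   `c(2, 2, 2, 2, 2, 3)` emulates a table of five pairs and one triplet);
#'   remaining species are singletons.
#' @param abundance_model `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog Lognormal parameters.
#' @param logseries_p Log-series parameter in (0, 1) (probability decay of
#'   the Fisher series).
#' @param tie_rate Probability that each adjacent pair of the
#'   abundance-sorted species is set equal.
#' @param integer_counts Round abundances to integer counts (default; set
#'   `FALSE` to keep continuous densities, which are almost surely
#'   tie-free when `tie_rate = 0`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A `community_table` tibble (`species`, `genus`, `guild`,
#'   `abundance`, `zero_abundance`).
#' @examples
#' tb <- generate_null_table(39, c(2, 2, 2, 2, 2, 3), seed = 1)
#' table(table(paste(tb$genus, tb$guild)))
#' @export
generate_null_table <- function(S, group_sizes = integer(0),
                                abundance_model = c("lognormal", "logseries"),
                                meanlog = 3, sdlog = 1.2, logseries_p = 0.95,
                                tie_rate = 0.1, integer_counts = TRUE,
                                seed = 20210316) {
  abundance_model <- rlang::arg_match(abundance_model)
  group_sizes <- as.integer(group_sizes)
  if (sum(group_sizes) > S) {
    rlang::abort("Group sizes exceed the species count.", class = "radlabel_spec_error")
  }
  if (any(group_sizes < 2L)) {
    rlang::abort("`group_sizes` lists multi-member groups only (each >= 2).",
                 class = "radlabel_spec_error")
  }
  withr::local_seed(seed)
  ab <- switch(abundance_model,
    lognormal = stats::rlnorm(S, meanlog = meanlog, sdlog = sdlog),
    logseries = rlogseries(S, logseries_p)
  )
  ab <- sort(ab, decreasing = TRUE)
  if (tie_rate > 0 && S > 1) {
    tie <- stats::runif(S - 1) < tie_rate
    for (i in which(tie)) ab[i + 1] <- ab[i]
  }
  if (integer_counts) ab <- pmax(round(ab), 1)
  ab <- sort(ab, decreasing = TRUE)  # rounding/tying cannot break the ordering

  # random label assignment: which species carry the multi-group labels
  genus <- paste0("Sing", seq_len(S))
  guild <- rep("X", S)
  if (length(group_sizes) > 0) {
    slots <- sample.int(S, sum(group_sizes))
    lab <- rep(seq_along(group_sizes), group_sizes)
    genus[slots] <- paste0("Gen", lab)
    guild[slots] <- "G"
  }
  structure(
    tibble::tibble(
      species = paste0("sp", formatC(seq_len(S), width = 3, flag = "0")),
      genus = genus,
      guild = guild,
      abundance = ab,
      zero_abundance = ab == 0
    ),
    class = c("community_table", "tbl_df", "tbl", "data.frame")
  )
}

# Fisher log-series abundance sampler: P(k) proportional to p^k / k
rlogseries <- function(n, p) {
  stopifnot(p > 0, p < 1)
  kmax <- max(1000L, ceiling(stats::qgeom(1 - 1e-12, 1 - p)))
  k <- seq_len(kmax)
  prob <- p^k / k
  sample(k, n, replace = TRUE, prob = prob)
}

#' Convert a model equilibrium into a grouped community table
#'
#' The alternative-hypothesis generator: runs the colonization model to
#' equilibrium, converts the included species' normalized frequencies into
#' integer abundances at a stated population scale, and labels maximal runs
#' of adjacent surviving grid neighbours as similarity groups (genus
#' `adj<k>`), so the quasi-exclusion signal of the model is carried into the
#' table's group structure.
#'
#' @param spec A [community_spec()] whose equilibrium has at least two
#'   survivors.
#' @param grouping `"runs"` (adjacency groups) or `"none"` (all singletons).
#' @param scale Population scale (total individuals), default 1,000.
#' @param threshold RAD inclusion threshold passed to [build_rad()].
#' @return A `community_table` tibble.
#' @examples
#' tb <- generate_structured_table(spec_from_fecundities(c(2, 5, 6), 1, 1))
#' tb$abundance  # 833 167
#' @export
generate_structured_table <- function(spec, grouping = c("runs", "none"),
                                      scale = 1000, threshold = 1e-7) {
  grouping <- rlang::arg_match(grouping)
  eq <- solve_equilibrium(spec)
  if (sum(eq$survivors) < 2L) {
    rlang::abort("Need at least two survivors to build a structured table.",
                 class = "radlabel_infeasible")
  }
  rad <- build_rad(eq, threshold = threshold)
  if (grouping == "runs") rad <- adjacency_groups(rad)
  ord <- order(rad$grid_index)
  key <- if (grouping == "runs") rad$group_key[ord] else paste0("s", rad$grid_index[ord])
  structure(
    tibble::tibble(
      species = rad$species_id[ord],
      genus = key,
      guild = "model",
      abundance = round(rad$frequency[ord] * scale),
      zero_abundance = round(rad$frequency[ord] * scale) == 0
    ),
    class = c("community_table", "tbl_df", "tbl", "data.frame")
  )
}

#' Ensemble of position-perturbed community specs
#'
#' Replicates a community spec with perturbed competitive-inferiority
#' positions, either jittered within half an interval of the even grid
#' (`jitter_half_interval`) or drawn completely at random over the domain
#' (`uniform_random`), for robustness analyses of the serrated pattern.
#'
#' @param spec A [community_spec()].
#' @param mode Perturbation mode.
#' @param n_replicates Number of replicate specs.
#' @param seed Integer seed; replicate `i` uses sub-seed `seed + i`.
#' @param relative_shift Grid shift passed through to [make_positions()].
#' @return List of `community_spec` objects.
#' @export
generate_perturbed_ensemble <- function(spec,
                                        mode = c("jitter_half_interval", "uniform_random"),
                                        n_replicates = 10, seed = 20210316,
                                        relative_shift = 0) {
  mode <- rlang::arg_match(mode)
  if (n_replicates < 1) {
    rlang::abort("`n_replicates` must be >= 1.", class = "radlabel_parameter_error")
  }
  lapply(seq_len(n_replicates), function(i) {
    pos <- make_positions(spec$n, spec$trade_off$x_hat,
                          relative_shift = relative_shift,
                          perturbation = mode, seed = seed + i)
    community_spec(pos, m = spec$m, q = spec$q, trade_off = spec$trade_off)
  })
}
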