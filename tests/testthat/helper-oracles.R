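# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force permutation enumeration for the rank
# test, plain quadrature for the continuous solution, and direct arithmetic
# for small equilibria.

# all permutations of 1..n (n! rows); plain recursion, no package code
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# brute-force null distribution of the two indices: labels is a character
# vector (NA = singleton), ranks the rank of each slot. Every one of the S!
# label permutations is visited with equal weight.
brute_force_rank_test <- function(ranks, labels, mode = "all_pairs",
                                  obs_labels = labels) {
  S <- length(ranks)
  perms <- all_perms(S)
  stat_one <- function(lab) {
    keys <- unique(lab[!is.na(lab)])
    dists <- c()
    members <- c()
    for (g in keys) {
      rv <- ranks[which(!is.na(lab) & lab == g)]
      if (length(rv) < 2L) next
      members <- c(members, rv)
      if (mode == "all_pairs") {
        for (i in seq_along(rv)) for (j in seq_along(rv)) {
          if (i < j) dists <- c(dists, abs(rv[i] - rv[j]))
        }
      } else {
        sv <- sort(rv)
        dists <- c(dists, sv[-1] - sv[-length(sv)])
      }
    }
    c(sd = stats::sd(dists), mean = mean(members))
  }
  obs <- stat_one(obs_labels)
  null <- apply(perms, 1L, function(pm) stat_one(labels[pm]))
  p_sd <- mean(null["sd", ] <= obs[["sd"]] + 1e-12)
  # baseline: closed-form expected mean rank (mean over every ranked slot);
  # trials exactly on the baseline belong to neither side
  grand <- mean(ranks)
  eps <- 1e-9 * max(1, abs(grand))
  side <- if (obs[["mean"]] < grand) "below" else "above"
  same <- if (side == "below") null["mean", ] < grand - eps
          else null["mean", ] > grand + eps
  extreme <- if (side == "below") null["mean", ] <= obs[["mean"]] + 1e-12
             else null["mean", ] >= obs[["mean"]] - 1e-12
  list(
    observed_sd = obs[["sd"]], observed_mean = obs[["mean"]],
    p_sd = p_sd, side = side,
    p_rank = sum(same & extreme) / sum(same),
    grand_mean = grand
  )
}

# random community spec with a random monotone trade-off (seeded by caller)
random_spec <- function(n_max = 20) {
  n <- sample.int(n_max, 1)
  x_hat <- stats::runif(1, 1, 4)
  shape <- sample(c("linear", "saturating", "sigmoid", "convex"), 1)
  to <- switch(shape,
    linear = trade_off("linear", c(a = stats::runif(1, 0.05, 0.5), b = stats::runif(1, 0.3, 2)), x_hat),
    saturating = trade_off("saturating",
      c(a = stats::runif(1, 0.05, 0.5), c = stats::runif(1, 0.5, 3), k = stats::runif(1, 0.5, 3)), x_hat),
    sigmoid = trade_off("sigmoid",
      c(a = stats::runif(1, 0.05, 0.5), c = stats::runif(1, 0.5, 3),
        k = stats::runif(1, 1, 4), x0 = stats::runif(1, 0.2, 0.8) * x_hat), x_hat),
    convex = trade_off("convex",
      c(a = stats::runif(1, 0.05, 0.5), b = stats::runif(1, 0.2, 1.5),
        gamma = stats::runif(1, 1.2, 3)), x_hat)
  )
  pos <- make_positions(n, x_hat, relative_shift = stats::runif(1))
  community_spec(pos, m = stats::runif(1, 0, 0.6), q = stats::runif(1, 0.5, 2), trade_off = to)
}

# toy grouped table used by several IO tests
toy_table <- function() {
  tibble::tibble(
    species = c("A", "B", "C", "D", "E", "F"),
    genus = c("Dermanura", "Dermanura", "Dermanura", "Myotis", "Myotis", "Sturnira"),
    guild = c("FRIN", "FRIN", "FRIN", "IN", "IN", "FR"),
    abundance = c(40, 12, 12, 9, 5, 2)
  )
}

write_toy_csv <- function(tb = toy_table(), path = tempfile(fileext = ".csv")) {
  readr::write_csv(tb, path, progress = FALSE)
  path
}
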