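#' Label peak and non-peak species on the competitiveness grid
#'
#' A peak species achieves a higher equilibrium frequency than both of its
#' grid neighbours on the competitiveness axis (extinct neighbours count with
#' frequency 0); a species at either end of the grid is compared against its
#' single neighbour only. Extinct species are neither peak nor non-peak.
#'
#' @param eq An `equilibrium_community`.
#' @return Logical vector: `TRUE` for peaks, `FALSE` for surviving non-peaks,
#'   `NA` for extinct species.
#' @examples
#' eq <- solve_equilibrium(spec_from_fecundities(c(2, 5, 6), m = 1, q = 1))
#' label_peaks(eq)  # TRUE FALSE NA
#' @export
label_peaks <- function(eq) {
  stopifnot(inherits(eq, "equilibrium_community"))
  p <- eq$frequencies
  n <- length(p)
  if (n == 1L) {
    peak <- TRUE
  } else {
    # -Inf padding makes each endpoint compare against its single neighbour only
    left <- c(-Inf, p[-n])
    right <- c(p[-1], -Inf)
    peak <- p > left & p > right
  }
  peak[!eq$survivors] <- NA
  peak
}

#' Build a rank abundance diagram from a community equilibrium
#'
#' Drops species with site frequency below `threshold` (default `1e-7`),
#' renormalizes the remaining frequencies to sum to 1 (this also removes
#' empty sites from the accounting), and assigns descending-frequency ranks
#' with competition ("min") ties: tied species share the smallest applicable
#' rank and the next distinct frequency skips accordingly. Peak flags are
#' carried along.
#'
#' @param eq An `equilibrium_community`.
#' @param threshold Inclusion threshold on site frequency.
#' @return A `rad_community`: a tibble with columns `species_id`, `group_key`
#'   (`NA` until a grouping is attached), `frequency` (normalized), `rank`,
#'   `peak`, carrying attributes `resolution` (the model's species count) and
#'   `threshold`.
#' @examples
#' eq <- solve_equilibrium(spec_from_fecundities(c(2, 5, 6), m = 1, q = 1))
#' build_rad(eq)
#' @export
build_rad <- function(eq, threshold = 1e-7) {
  stopifnot(inherits(eq, "equilibrium_community"))
  keep <- which(eq$frequencies >= threshold)
  if (length(keep) == 0L) {
    rlang::abort("All species fall below the inclusion threshold: empty RAD.",
                 class = "radlabel_empty_rad")
  }
  p <- eq$frequencies[keep]
  peaks <- label_peaks(eq)[keep]
  new_rad(
    species_id = paste0("sp", formatC(keep, width = 3, flag = "0")),
    frequency = p / sum(p),
    rank = rank_min_desc(p),
    peak = peaks,
    group_key = NA_character_,
    grid_index = keep,
    resolution = eq$spec$n,
    threshold = threshold
  )
}

rank_min_desc <- function(abundance) {
  as.integer(rank(-abundance, ties.method = "min"))
}

new_rad <- function(species_id, frequency, rank, peak = NA, group_key = NA_character_,
                    grid_index = NA_integer_, resolution = NA_integer_, threshold = NA_real_,
                    extra = NULL) {
  tb <- tibble::tibble(
    species_id = species_id,
    group_key = group_key,
    frequency = frequency,
    rank = as.integer(rank),
    peak = peak,
    grid_index = grid_index
  )
  if (!is.null(extra)) tb <- dplyr::bind_cols(tb, extra)
  tb <- dplyr::arrange(tb, rank, dplyr::desc(frequency), species_id)
  structure(tb, class = c("rad_community", class(tb)),
            resolution = resolution, threshold = threshold)
}

#' Tie structure of a RAD
#'
#' @param rad A `rad_community`.
#' @return A tibble mapping each occupied `rank` to the number of species
#'   sharing it.
#' @export
tie_structure <- function(rad) {
  dplyr::count(tibble::as_tibble(rad), rank, name = "n_species")
}

#' Simpson's diversity index of a RAD
#'
#' `1 - sum(p_i^2)` over the normalized included frequencies: the probability
#' that two randomly drawn individuals belong to different species. Bounded
#' by `1 - 1/S` for `S` included species.
#'
#' @param rad A `rad_community`.
#' @return A single value in `[0, 1 - 1/S]`.
#' @examples
#' eq <- solve_equilibrium(spec_from_fecundities(c(2, 5, 6), m = 1, q = 1))
#' simpson_index(build_rad(eq))  # 1 - 26/36
#' @export
simpson_index <- function(rad) {
  stopifnot(inherits(rad, "rad_community"))
  1 - sum(rad$frequency^2)
}

#' Species abundance distribution histograms
#'
#' Translates a RAD into the two SAD views: frequencies are min-max rescaled
#' to `[0, 1]` (0 = rarest included species, 1 = most abundant) and counted
#' into 11 classes at a 0.1 interval — class `k` covers
#' `[(k-1)/10, k/10)` for `k = 1..10` and class 11 holds the maximum. The
#' linear histogram rescales the raw frequencies; the log2 histogram applies
#' the same rescaling to `log2(frequency)` (always finite, because only
#' included species enter).
#'
#' @param rad A `rad_community` with at least two species of distinct
#'   frequency.
#' @return A list of two `sad_histogram` objects (`linear`, `log2`), each a
#'   tibble with columns `class` (1-11), `lower`, `upper`, `count`.
#' @export
sad_histograms <- function(rad) {
  stopifnot(inherits(rad, "rad_community"))
  if (nrow(rad) < 2L || max(rad$frequency) == min(rad$frequency)) {
    rlang::abort("SAD histograms need >= 2 species with distinct min and max frequency.",
                 class = "radlabel_degenerate_histogram")
  }
  list(
    linear = sad_histogram_one(rad$frequency, "linear"),
    log2 = sad_histogram_one(log2(rad$frequency), "log2")
  )
}

sad_histogram_one <- function(v, scale) {
  z <- (v - min(v)) / (max(v) - min(v))
  cls <- pmin(floor(z * 10), 10) + 1L   # z = 1 -> class 11; pmin guards rounding
  cls[z >= 1] <- 11L
  counts <- tabulate(cls, nbins = 11L)
  structure(
    tibble::tibble(
      class = 1:11,
      lower = (0:10) / 10,
      upper = c((1:10) / 10, 1),
      count = counts
    ),
    class = c("sad_histogram", "tbl_df", "tbl", "data.frame"),
    scale = scale
  )
}

#' Deviation of the discrete equilibrium from the continuous solution
#'
#' Measures the serration of a discrete community against its continuous
#' baseline: each species is assigned the analytic frequency of its
#' half-interval cell `[x_i - h/2, x_i + h/2]` (with `h = x_hat/n`) truncated
#' to the viable range `[x_c, x_hat]`, and the index is the mean of
#' `|p_numeric - p_analytic| / p_analytic` over species whose analytic cell
#' frequency is positive.
#'
#' @param spec A [community_spec()]; its trade-off must be viable
#'   (`f(x_hat) > m/q`).
#' @return Mean relative deviation (dimensionless, `>= 0`).
#' @export
deviation_index <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  ce <- continuous_equilibrium(spec$trade_off, spec$m, spec$q)
  x_hat <- spec$trade_off$x_hat
  h <- x_hat / spec$n
  lo <- pmax(spec$positions - h / 2, ce$x_c)
  hi <- pmin(spec$positions + h / 2, x_hat)
  width <- pmax(hi - lo, 0)
  p_analytic <- ifelse(width > 0, interval_frequency(ce, pmin(lo, x_hat), width), 0)
  keep <- p_analytic > 0
  if (!any(keep)) {
    rlang::abort("No species has a positive analytic cell frequency.",
                 class = "radlabel_undefined_index")
  }
  p_num <- solve_equilibrium(spec)$frequencies
  mean(abs(p_num[keep] - p_analytic[keep]) / p_analytic[keep])
}

#' Fraction of survivors with a surviving grid neighbour
#'
#' The label printed under each model RAD: how many surviving species have at
#' least one surviving species at an adjacent grid position (numerator), out
#' of all survivors (denominator).
#'
#' @param eq An `equilibrium_community`.
#' @return Named numeric vector `c(numerator = , denominator = )`.
#' @export
neighbor_survival_fraction <- function(eq) {
  stopifnot(inherits(eq, "equilibrium_community"))
  s <- eq$survivors
  n <- length(s)
  if (n == 1L) {
    return(c(numerator = 0, denominator = sum(s)))
  }
  left <- c(FALSE, s[-n])
  right <- c(s[-1], FALSE)
  c(numerator = sum(s & (left | right)), denominator = sum(s))
}

#' Group model species by adjacency on the competitiveness axis
#'
#' The model analogue of "similar species": maximal runs of surviving species
#' at consecutive grid positions form one group each; isolated survivors are
#' singletons. Attaches the grouping to the RAD's `group_key` column
#' (`"adj<k>"` for run `k`, `"s<i>"` singletons).
#'
#' @param rad A `rad_community` built by [build_rad()] (its `grid_index`
#'   column links species back to the competitiveness grid).
#' @return The RAD with `group_key` filled in.
#' @export
adjacency_groups <- function(rad) {
  stopifnot(inherits(rad, "rad_community"))
  if (any(is.na(rad$grid_index))) {
    rlang::abort("RAD has no grid positions; adjacency grouping needs a model RAD.",
                 class = "radlabel_parameter_error")
  }
  ord <- order(rad$grid_index)
  gi <- rad$grid_index[ord]
  run_id <- cumsum(c(1L, as.integer(diff(gi) > 1L)))
  sizes <- table(run_id)
  key <- ifelse(sizes[as.character(run_id)] >= 2L,
                paste0("adj", run_id),
                paste0("s", gi))
  rad$group_key[ord] <- key
  rad
}

#' @export
print.rad_community <- function(x, ...) {
  cat("<rad_community> species:", nrow(x),
      " resolution:", attr(x, "resolution"),
      " threshold:", attr(x, "threshold"), "\n")
  NextMethod()
}
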