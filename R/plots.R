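#' Plot a labeled rank abundance diagram
#'
#' Log abundance against descending abundance rank, the standard RAD view.
#' Peak species (frequency above both grid neighbours) are drawn as solid
#' dots and non-peak species as open dots where peak flags are available;
#' for grouped empirical RADs, species of multi-member groups are coloured by
#' group and singletons are grey.
#'
#' @param object A `rad_community`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_community <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  has_peaks <- !all(is.na(tb$peak))
  if (has_peaks) {
    tb$type <- ifelse(tb$peak, "peak", "non-peak")
    p <- ggplot2::ggplot(tb, ggplot2::aes(x = rank, y = frequency, shape = type)) +
      ggplot2::geom_point(size = 2.4) +
      ggplot2::scale_shape_manual(values = c(peak = 16, `non-peak` = 1))
  } else {
    sizes <- table(tb$group_key[!is.na(tb$group_key)])
    multi <- names(sizes)[sizes >= 2]
    tb$group <- ifelse(tb$group_key %in% multi, tb$group_key, NA_character_)
    p <- ggplot2::ggplot(tb, ggplot2::aes(x = rank, y = frequency, colour = group)) +
      ggplot2::geom_point(size = 2.4) +
      ggplot2::scale_colour_discrete(na.value = "grey70")
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Abundance rank", y = "Normalized frequency (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot an equilibrium frequency distribution over competitiveness
#'
#' The serration view: discrete equilibrium frequencies as vertical bars over
#' competitive inferiority, with the continuous-competitiveness analytic
#' per-cell frequency overlaid as a broken curve when the continuous
#' solution is viable.
#'
#' @param object An `equilibrium_community`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equilibrium_community <- function(object, ...) {
  tb <- tidy.equilibrium_community(object)
  spec <- object$spec
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = x, y = p)) +
    ggplot2::geom_col(width = spec$trade_off$x_hat / spec$n * 0.8, fill = "grey40") +
    ggplot2::labs(x = "Competitive inferiority x", y = "Equilibrium site frequency") +
    ggplot2::theme_minimal()
  analytic <- tryCatch({
    ce <- continuous_equilibrium(spec$trade_off, spec$m, spec$q)
    h <- spec$trade_off$x_hat / spec$n
    lo <- pmax(tb$x - h / 2, ce$x_c)
    hi <- pmin(tb$x + h / 2, spec$trade_off$x_hat)
    w <- pmax(hi - lo, 0)
    ifelse(w > 0, interval_frequency(ce, pmin(lo, spec$trade_off$x_hat), w), 0)
  }, error = function(e) NULL)
  if (!is.null(analytic)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(x = tb$x, p = analytic),
      linetype = "dashed", colour = "grey55"
    )
  }
  p
}

#' Plot a SAD histogram
#'
#' @param object A `sad_histogram` from [sad_histograms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sad_histogram <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = (lower + upper) / 2, y = count)) +
    ggplot2::geom_col(width = 0.09, fill = "grey40") +
    ggplot2::labs(
      x = paste0("Normalized frequency (", attr(object, "scale"), " scale)"),
      y = "Number of species"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the null distributions of a rank test
#'
#' Histograms of the randomized rank-distance SD and mean rank, with the
#' observed values as dotted vertical lines and the grand-mean baseline of
#' the conditional rank test as a dashed line.
#'
#' @param object A `rank_test_result` with kept null vectors.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @export
autoplot.rank_test_result <- function(object, ...) {
  tb <- tidy.rank_test_result(object)
  long <- tidyr::pivot_longer(tb, c(null_sd, null_mean_rank),
                              names_to = "index", values_to = "value")
  obs <- tibble::tibble(
    index = c("null_sd", "null_mean_rank"),
    value = c(object$observed_sd, object$observed_mean_rank)
  )
  base <- tibble::tibble(index = "null_mean_rank", value = object$null_mean_mean)
  ggplot2::ggplot(long, ggplot2::aes(x = value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = value),
                        linetype = "dotted", linewidth = 0.8) +
    ggplot2::geom_vline(data = base, ggplot2::aes(xintercept = value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = "Index value under randomization", y = "Trials") +
    ggplot2::theme_minimal()
}
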