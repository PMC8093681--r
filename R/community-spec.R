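#' Species positions on the competitiveness axis
#'
#' Places `n` species at competitive inferiority values on `[0, x_hat]`.
#' The base layout is an even grid with interval `h = x_hat / n`: species `i`
#' sits at `(i - 1) h + relative_shift * h`, so a relative shift of 0 starts
#' the community at `x = 0` and a shift of 1 ends it at `x_hat`. Two
#' perturbation modes emulate operational noise in the trade-off:
#' `jitter_half_interval` adds independent uniform noise on `±h/2` to each base
#' position, and `uniform_random` discards the grid entirely, drawing `n`
#' positions uniformly on `[0, x_hat]`. Perturbed positions are sorted,
#' clamped to the domain, and de-tied with a minimal separation of `1e-12`.
#'
#' @param n Number of species (positive integer).
#' @param x_hat Upper bound of competitive inferiority.
#' @param relative_shift Shift of the whole grid, in units of the interval
#'   `h = x_hat / n`; must lie in `[0, 1]`.
#' @param perturbation `"none"`, `"jitter_half_interval"`, or
#'   `"uniform_random"`.
#' @param seed Integer seed for the stochastic modes (required there);
#'   ignored for `"none"`.
#' @return Strictly increasing numeric vector of length `n`.
#' @examples
#' make_positions(5, x_hat = 2.5)            # 0.0 0.5 1.0 1.5 2.0
#' make_positions(5, 2.5, relative_shift = 1)  # 0.5 1.0 1.5 2.0 2.5
#' @export
make_positions <- function(n, x_hat = 2.5, relative_shift = 0,
                           perturbation = c("none", "jitter_half_interval", "uniform_random"),
                           seed = NULL) {
  perturbation <- rlang::arg_match(perturbation)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer.", class = "radlabel_parameter_error")
  }
  if (relative_shift < 0 || relative_shift > 1) {
    rlang::abort("`relative_shift` must lie in [0, 1].", class = "radlabel_parameter_error")
  }
  h <- x_hat / n
  base <- (seq_len(n) - 1) * h + relative_shift * h

  if (perturbation == "none") {
    return(base)
  }
  if (is.null(seed)) {
    rlang::abort("Stochastic perturbation modes require a `seed`.",
                 class = "radlabel_parameter_error")
  }
  withr::local_seed(seed)
  x <- if (perturbation == "jitter_half_interval") {
    pmin(pmax(base + stats::runif(n, -h / 2, h / 2), 0), x_hat)
  } else {
    stats::runif(n, 0, x_hat)
  }
  x <- sort(x)
  # enforce strict increase; minimal separation guards exact collisions
  for (i in seq_len(n)[-1]) {
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1e-12
  }
  x
}

#' Specify a discrete-competitiveness community
#'
#' Bundles the ingredients of the colonization model: `n` species at strictly
#' increasing competitive inferiority positions `x_1 < ... < x_n`, a colony
#' destruction rate `m`, a propagule encounter rate `q`, and a
#' competition-fecundity [trade_off()]. Fecundities `f_i = f(x_i)` are then
#' strictly increasing in `i` (species 1 is the best competitor with the
#' lowest fecundity).
#'
#' @param positions Strictly increasing vector of competitive inferiority
#'   values within `[0, x_hat]` of the trade-off.
#' @param m Colony destruction (mortality/disturbance) rate, `m >= 0`.
#' @param q Propagule encounter rate, `q > 0`.
#' @param trade_off A [trade_off()] object.
#' @return An object of class `community_spec` with elements `n`, `positions`,
#'   `f` (fecundities), `m`, `q`, `trade_off`.
#' @examples
#' to <- trade_off("linear", c(a = 1, b = 1), x_hat = 2.5)
#' spec <- community_spec(make_positions(5, 2.5), m = 1, q = 1, trade_off = to)
#' spec$f
#' @export
community_spec <- function(positions, m, q, trade_off) {
  stopifnot(inherits(trade_off, "trade_off"))
  if (length(positions) < 1L || any(diff(positions) <= 0)) {
    rlang::abort("`positions` must be non-empty and strictly increasing.",
                 class = "radlabel_parameter_error")
  }
  if (any(positions < 0 | positions > trade_off$x_hat)) {
    rlang::abort("`positions` must lie within [0, x_hat].",
                 class = "radlabel_domain_error")
  }
  if (m < 0) rlang::abort("`m` must be >= 0.", class = "radlabel_parameter_error")
  if (q <= 0) rlang::abort("`q` must be > 0.", class = "radlabel_parameter_error")
  f <- trade_off$f(positions)
  if (any(diff(f) <= 0)) {
    rlang::abort("Fecundities f(x_i) must be strictly increasing.",
                 class = "radlabel_parameter_error")
  }
  structure(
    list(n = length(positions), positions = as.numeric(positions),
         f = as.numeric(f), m = m, q = q, trade_off = trade_off),
    class = "community_spec"
  )
}

#' Construct a community spec directly from fecundities
#'
#' Convenience wrapper used in worked examples and tests: supplies an
#' increasing fecundity vector without going through a parametric trade-off.
#' Positions are taken as `1, 2, ..., n` and the trade-off is a monotone
#' interpolant through `(i, f_i)`.
#'
#' @param f Strictly increasing positive fecundity vector.
#' @inheritParams community_spec
#' @return A `community_spec`.
#' @examples
#' spec_from_fecundities(c(2, 5, 6), m = 1, q = 1)
#' @export
spec_from_fecundities <- function(f, m, q) {
  if (any(diff(f) <= 0) || any(f <= 0)) {
    rlang::abort("`f` must be positive and strictly increasing.",
                 class = "radlabel_parameter_error")
  }
  n <- length(f)
  xs <- seq_len(n)
  interp <- stats::approxfun(c(0, xs), c(max(f[1] / 2, 1e-8), f), rule = 2)
  to <- trade_off("user", x_hat = n, f = interp)
  community_spec(xs, m = m, q = q, trade_off = to)
}

#' Gap-dynamics variant of a community spec
#'
#' For forest-gap dynamics where disturbances open invadable gaps at rate `g`
#' and only gaps can be colonized, the site-frequency dynamics keep the same
#' structure with the effective encounter rate `q' = q g`. This returns the
#' same community with `q` replaced by `q * g`; every downstream operation
#' then models the gap system.
#'
#' @param spec A [community_spec()].
#' @param g Gap formation rate, `g > 0`.
#' @return A `community_spec` with encounter rate `q * g`.
#' @examples
#' spec <- spec_from_fecundities(c(2, 5, 6), m = 1, q = 2)
#' gap_variant(spec, g = 0.5)$q  # 1
#' @export
gap_variant <- function(spec, g) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    rlang::abort("`g` must be a single positive number.", class = "radlabel_parameter_error")
  }
  out <- spec
  out$q <- spec$q * g
  out
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> n:", x$n, " m:", x$m, " q:", x$q,
      " trade-off:", x$trade_off$family, "\n")
  invisible(x)
}
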