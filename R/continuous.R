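#' Critical competitive inferiority
#'
#' The continuous-competitiveness community occupies `[x_c, x_hat]`, where
#' `x_c` solves `f(x_c) = m/q`: no species with fecundity at or below the
#' destruction-to-encounter ratio can persist. If `f(0) >= m/q` the whole
#' domain is viable and `x_c = 0`; if `f(x_hat) <= m/q` no species is viable
#' and an error of class `radlabel_no_viable_species` is signalled. The root
#' is located by bisection to absolute tolerance `1e-10` (robust to
#' non-differentiable user-supplied trade-offs).
#'
#' @param trade_off A [trade_off()] object.
#' @param m Colony destruction rate.
#' @param q Propagule encounter rate, `q > 0`.
#' @return The critical inferiority `x_c` in `[0, x_hat]`.
#' @examples
#' to <- trade_off("linear", c(a = 1, b = 1), x_hat = 2.5)
#' critical_inferiority(to, m = 1.5, q = 1)  # 0.5
#' @export
critical_inferiority <- function(trade_off, m, q) {
  stopifnot(inherits(trade_off, "trade_off"))
  if (q <= 0) rlang::abort("`q` must be > 0.", class = "radlabel_parameter_error")
  moq <- m / q
  if (trade_off$f(0) >= moq) return(0)
  if (trade_off$f(trade_off$x_hat) <= moq) {
    rlang::abort("No viable species: f(x_hat) <= m/q, the continuous community is empty.",
                 class = "radlabel_no_viable_species")
  }
  lo <- 0
  hi <- trade_off$x_hat
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (trade_off$f(mid) < moq) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Continuous-competitiveness equilibrium
#'
#' In the limit of infinitely many species the equilibrium becomes a density
#' of site frequency over competitive inferiority,
#' \deqn{p(x) = \tfrac{1}{2} f'(x)\, f(x)^{-3/2} \sqrt{m/q},
#'   \qquad x_c \le x \le \hat x,}
#' whose integral over an interval telescopes to the closed interval
#' frequency of [interval_frequency()]. This constructor computes `x_c` and
#' bundles the pieces.
#'
#' When `x_c` is an interior root (`f(0) < m/q`) the density integrates to
#' the total occupied fraction `1 - sqrt((m/q)/f(x_hat))` over
#' `[x_c, x_hat]`. When instead `f(0) >= m/q`, `x_c` clamps to 0 and the
#' continuous solution additionally concentrates a boundary atom of
#' frequency `1 - sqrt((m/q)/f(0))` on the best competitor at `x = 0`; the
#' density itself then accounts only for the remaining
#' `sqrt(m/q) (f(0)^(-1/2) - f(x_hat)^(-1/2))`.
#'
#' @inheritParams critical_inferiority
#' @return An object of class `continuous_equilibrium` with `trade_off`, `m`,
#'   `q`, `x_c`, and a vectorised `density` function.
#' @examples
#' to <- trade_off("linear", c(a = 1, b = 1), x_hat = 2.5)
#' ce <- continuous_equilibrium(to, m = 1, q = 1)
#' ce$x_c                       # 0
#' continuous_density(ce, 0)    # 0.5
#' @export
continuous_equilibrium <- function(trade_off, m, q) {
  x_c <- critical_inferiority(trade_off, m, q)
  obj <- structure(
    list(trade_off = trade_off, m = m, q = q, x_c = x_c),
    class = "continuous_equilibrium"
  )
  obj$density <- function(x) continuous_density(obj, x)
  obj
}

#' Equilibrium abundance density at a point
#'
#' Evaluates `p(x) = (1/2) f'(x) f(x)^(-3/2) sqrt(m/q)` on `[x_c, x_hat]`.
#'
#' @param ce A [continuous_equilibrium()].
#' @param x Point(s) in `[x_c, x_hat]`.
#' @return Density value(s), always `>= 0`.
#' @export
continuous_density <- function(ce, x) {
  stopifnot(inherits(ce, "continuous_equilibrium"))
  if (any(x < ce$x_c - 1e-12 | x > ce$trade_off$x_hat + 1e-12)) {
    rlang::abort("`x` outside [x_c, x_hat].", class = "radlabel_domain_error")
  }
  to <- ce$trade_off
  0.5 * to$fprime(x) * to$f(x)^(-1.5) * sqrt(ce$m / ce$q)
}

#' Equilibrium frequency over an inferiority interval
#'
#' The substantial site frequency carried by species in `[x, x + dx]` is the
#' integral of the abundance density, which has the closed form
#' \deqn{p(x; x+\Delta x) = \Big(f(x)^{-1/2} - f(x+\Delta x)^{-1/2}\Big)\sqrt{m/q}.}
#' Over the full viable range `[x_c, x_hat]` this telescopes to
#' `1 - sqrt((m/q)/f(x_hat))` because `f(x_c) = m/q`.
#'
#' @param ce A [continuous_equilibrium()].
#' @param x Left endpoint, `x >= x_c`.
#' @param dx Interval width, `dx >= 0`, with `x + dx <= x_hat`.
#' @return Frequency in `[0, 1]`.
#' @examples
#' to <- trade_off("linear", c(a = 1, b = 1), x_hat = 2.5)
#' ce <- continuous_equilibrium(to, m = 1.5, q = 1)
#' interval_frequency(ce, ce$x_c, 2.5 - ce$x_c)  # total occupied fraction
#' @export
interval_frequency <- function(ce, x, dx) {
  stopifnot(inherits(ce, "continuous_equilibrium"))
  if (any(dx < 0)) rlang::abort("`dx` must be >= 0.", class = "radlabel_parameter_error")
  if (any(x < ce$x_c - 1e-12) || any(x + dx > ce$trade_off$x_hat + 1e-12)) {
    rlang::abort("Interval outside [x_c, x_hat].", class = "radlabel_domain_error")
  }
  f <- ce$trade_off$f
  (f(x)^(-0.5) - f(x + dx)^(-0.5)) * sqrt(ce$m / ce$q)
}

#' @export
print.continuous_equilibrium <- function(x, ...) {
  cat("<continuous_equilibrium> x_c:", signif(x$x_c, 6),
      " x_hat:", x$trade_off$x_hat,
      " occupied mass:", signif(interval_frequency(x, x$x_c, x$trade_off$x_hat - x$x_c), 6),
      "\n")
  invisible(x)
}
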