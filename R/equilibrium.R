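#' Equilibrium of the colonization model by forward recursion
#'
#' Under displacement (dominance) competition, the equilibrium site frequency
#' of each species depends only on its own fecundity and on the species above
#' it in the competitive hierarchy, so the whole equilibrium is obtained by a
#' single forward pass from the best competitor down:
#' \deqn{p_i = 1 - \sum_{j<i} p_j - \frac{1}{f_i}\Big(\sum_{j<i} f_j p_j + m/q\Big)}
#' taken when positive and set to 0 otherwise. The first surviving species is
#' the first `i` with `f_i > m/q`. Values at or below `1e-15` are clamped to
#' exactly 0 before the recursion proceeds (floating-point guard on the
#' "if positive" clause).
#'
#' @param spec A [community_spec()].
#' @return An object of class `equilibrium_community`: a list with `spec`,
#'   `frequencies` (vector `p_i`), `survivors` (`p_i > 0`),
#'   `empty_fraction` (`1 - sum(p)`), and `converged = TRUE` (exact solution).
#' @examples
#' eq <- solve_equilibrium(spec_from_fecundities(c(2, 5, 6), m = 1, q = 1))
#' eq$frequencies  # 0.5 0.1 0.0 -- quasi-exclusion in miniature
#' @seealso [integrate_to_steady_state()] for the dynamical route,
#'   [tidy.equilibrium_community()] for a tabular view.
#' @export
solve_equilibrium <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  n <- spec$n
  f <- spec$f
  moq <- spec$m / spec$q
  p <- numeric(n)
  cum_p <- 0
  cum_fp <- 0
  for (i in seq_len(n)) {
    pi <- 1 - cum_p - (cum_fp + moq) / f[i]
    if (pi <= 1e-15) pi <- 0
    p[i] <- pi
    cum_p <- cum_p + pi
    cum_fp <- cum_fp + f[i] * pi
  }
  new_equilibrium(spec, p, converged = TRUE)
}

new_equilibrium <- function(spec, p, converged, survivor_threshold = 0) {
  structure(
    list(spec = spec, frequencies = p, survivors = p > survivor_threshold,
         empty_fraction = 1 - sum(p), converged = converged),
    class = "equilibrium_community"
  )
}

#' Right-hand side of the colonization dynamics
#'
#' Continuous-time site-frequency dynamics under dominance competition:
#' \deqn{\frac{dp_i}{dt} = q f_i p_i\Big(1 - \sum_{j \le i} p_j\Big)
#'   - q \Big(\sum_{j<i} f_j p_j\Big) p_i - m p_i.}
#' The first term is colonization of sites that are empty or held by inferior
#' species, the second is displacement by superior species, the third is
#' colony destruction.
#'
#' @param spec A [community_spec()].
#' @param p Frequency vector with `p_i >= 0` and `sum(p) <= 1`.
#' @return Vector of rates `dp_i/dt`.
#' @examples
#' spec <- spec_from_fecundities(c(2, 5, 6), m = 1, q = 1)
#' dynamics_rhs(spec, c(0.5, 0.1, 0))  # ~0: the equilibrium is a fixed point
#' @export
dynamics_rhs <- function(spec, p) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(p) != spec$n) {
    rlang::abort("`p` must have one entry per species.", class = "radlabel_state_error")
  }
  if (any(p < 0) || sum(p) > 1 + 1e-9) {
    rlang::abort("Invalid state: frequencies must be >= 0 and sum to at most 1.",
                 class = "radlabel_state_error")
  }
  rhs_raw(spec, p)
}

# unvalidated RHS shared with the integrator (which may wander a hair negative)
rhs_raw <- function(spec, p) {
  f <- spec$f
  cum_p <- cumsum(p)
  cum_fp_excl <- c(0, cumsum(f * p)[-spec$n])
  spec$q * f * p * (1 - cum_p) - spec$q * cum_fp_excl * p - spec$m * p
}

#' Integrate the colonization dynamics to steady state
#'
#' Integrates the site-frequency ODE with an adaptive stiff-capable scheme
#' (`deSolve::ode`, `lsoda`, relative tolerance `1e-10`, absolute `1e-12`)
#' over successively longer horizons until the maximal rate `max |dp/dt|`
#' falls below `tol`, or `t_max` is reached. Non-convergence is flagged on
#' the returned object (carrying the last state), not raised as an error.
#'
#' Because an ODE state is never exactly zero, survivor flags on the result
#' use the RAD inclusion threshold `1e-7` rather than strict positivity.
#'
#' @param spec A [community_spec()].
#' @param p0 Initial frequencies, all `> 0`, `sum <= 1`; default `1e-3` each.
#' @param tol Steady-state declaration threshold on `max |dp/dt|`.
#' @param t_max Integration horizon.
#' @return An `equilibrium_community` with a `converged` flag.
#' @examples
#' spec <- spec_from_fecundities(c(2, 5, 6), m = 1, q = 1)
#' round(integrate_to_steady_state(spec)$frequencies, 6)  # 0.5 0.1 0
#' @export
integrate_to_steady_state <- function(spec, p0 = NULL, tol = 1e-12, t_max = 1e8) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(p0)) p0 <- rep(1e-3, spec$n)
  if (any(p0 <= 0) || sum(p0) > 1) {
    rlang::abort("`p0` must be strictly positive with sum <= 1.",
                 class = "radlabel_state_error")
  }
  deriv <- function(t, y, parms) list(rhs_raw(spec, pmax(y, 0)))
  # per-capita growth rate; a species pinned at 0 with positive invasion
  # fitness is not at a true equilibrium and must be re-seeded (guards
  # against numerical absorption when the solver steps a tiny state negative)
  invasion_rate <- function(p) {
    cum_p <- cumsum(p)
    cum_fp_excl <- c(0, cumsum(spec$f * p)[-spec$n])
    spec$q * spec$f * (1 - cum_p) - spec$q * cum_fp_excl - spec$m
  }
  at_rest <- function(p) {
    max(abs(rhs_raw(spec, p))) < tol &&
      !any(p < 1e-10 & invasion_rate(p) > 1e-10)
  }
  p <- p0
  t_hi <- 10
  converged <- at_rest(p)
  while (!converged && t_hi <= t_max) {
    p[p < 1e-10 & invasion_rate(p) > 1e-10] <- 1e-8
    sol <- deSolve::ode(y = p, times = c(0, t_hi), func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    p <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    converged <- at_rest(p)
    t_hi <- t_hi * 10
  }
  new_equilibrium(spec, p, converged = converged, survivor_threshold = 1e-7)
}

#' @export
print.equilibrium_community <- function(x, ...) {
  cat("<equilibrium_community> n:", x$spec$n,
      " survivors:", sum(x$survivors),
      " empty fraction:", signif(x$empty_fraction, 4),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Tidy a community equilibrium into a per-species tibble
#'
#' @param x An `equilibrium_community`.
#' @param ... Unused.
#' @return A tibble with columns `index`, `x`, `f`, `p`, `survivor`, `peak`
#'   (`NA` for extinct species).
#' @export
tidy.equilibrium_community <- function(x, ...) {
  # assemble outside tibble() so the `x` column cannot mask the object
  tb <- list(
    index = seq_len(x$spec$n),
    x = x$spec$positions,
    f = x$spec$f,
    p = x$frequencies,
    survivor = x$survivors,
    peak = label_peaks(x)
  )
  tibble::as_tibble(tb)
}

#' One-row summary of a community equilibrium
#'
#' @param x An `equilibrium_community`.
#' @param ... Unused.
#' @return A one-row tibble: species count, survivor count, fraction of
#'   survivors with a surviving grid neighbour, empty-site fraction, the
#'   extinction threshold `m/q`, and convergence flag.
#' @export
glance.equilibrium_community <- function(x, ...) {
  nf <- neighbor_survival_fraction(x)
  tibble::tibble(
    n = x$spec$n,
    n_survivors = sum(x$survivors),
    n_with_surviving_neighbor = nf[["numerator"]],
    empty_fraction = x$empty_fraction,
    extinction_threshold = x$spec$m / x$spec$q,
    converged = x$converged
  )
}
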