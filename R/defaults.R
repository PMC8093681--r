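#' Reference trade-off shapes
#'
#' The exact trade-off curves behind published example figures of this model
#' family are generally not printed, so the package ships one qualitative
#' representative per shape, on the standard domain `x_hat = 2.5`:
#'
#' * `"linear"`: `f(x) = 0.1 + x`
#' * `"saturating"`: `f(x) = 0.1 + 2 (1 - exp(-2 x))` (concave, fecundity
#'   capped near 2.1 by environmental limits)
#' * `"sigmoid"`: `f(x) = 0.05 + 2 / (1 + exp(-3 (x - 1.2)))`
#' * `"convex"`: `f(x) = 0.1 + 0.4 x^2`
#'
#' With the default rates `m = 0.2`, `q = 1` every reference shape has
#' `f(0) < m/q < f(x_hat)`: the critical inferiority `x_c` is interior, the
#' least-fecund end of the axis is non-viable, and the serrated
#' quasi-exclusion regime appears at moderate resolutions. (When instead
#' `f(0) >= m/q`, the continuous solution concentrates a boundary atom of
#' frequency `1 - sqrt((m/q)/f(0))` on the best competitor at `x = 0`, on
#' top of the density.)
#'
#' @param shape One of `"linear"`, `"saturating"`, `"sigmoid"`, `"convex"`.
#' @param x_hat Domain bound.
#' @return A [trade_off()].
#' @export
reference_trade_off <- function(shape = c("saturating", "linear", "sigmoid", "convex"),
                                x_hat = 2.5) {
  shape <- rlang::arg_match(shape)
  switch(shape,
    linear = trade_off("linear", c(a = 0.1, b = 1), x_hat = x_hat),
    saturating = trade_off("saturating", c(a = 0.1, c = 2, k = 2), x_hat = x_hat),
    sigmoid = trade_off("sigmoid", c(a = 0.05, c = 2, k = 3, x0 = 1.2), x_hat = x_hat),
    convex = trade_off("convex", c(a = 0.1, b = 0.4, gamma = 2), x_hat = x_hat)
  )
}

#' Reference model community
#'
#' Convenience constructor for a discrete community on the even grid with a
#' reference trade-off and the default rates `m = 0.2`, `q = 1`.
#'
#' @inheritParams reference_trade_off
#' @param n Resolution (species count).
#' @param m,q Rates.
#' @param relative_shift,perturbation,seed Passed to [make_positions()].
#' @return A [community_spec()].
#' @examples
#' eq <- solve_equilibrium(reference_community("saturating", n = 30))
#' sum(eq$survivors)
#' @export
reference_community <- function(shape = c("saturating", "linear", "sigmoid", "convex"),
                                n = 30, m = 0.2, q = 1, x_hat = 2.5,
                                relative_shift = 0,
                                perturbation = "none", seed = NULL) {
  to <- reference_trade_off(shape, x_hat = x_hat)
  pos <- make_positions(n, x_hat, relative_shift = relative_shift,
                        perturbation = perturbation, seed = seed)
  community_spec(pos, m = m, q = q, trade_off = to)
}
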