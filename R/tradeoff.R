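#' Competition-fecundity trade-off functions
#'
#' A trade-off object represents a fecundity function `f(x)` that increases
#' monotonically with competitive inferiority `x` on the domain `[0, x_hat]`.
#' Larger `x` means a weaker competitor with higher fecundity; `x_hat` is the
#' upper bound of competitive inferiority in the system under study.
#'
#' Four parametric families are shipped, spanning the qualitative shapes a
#' saturating cost of competitiveness can take:
#'
#' * `linear`: `f(x) = a + b x` (params `a`, `b`)
#' * `saturating`: `f(x) = a + c (1 - exp(-k x))` (params `a`, `c`, `k`)
#' * `convex`: `f(x) = a + b x^gamma`, `gamma > 1` (params `a`, `b`, `gamma`)
#' * `sigmoid`: `f(x) = a + c / (1 + exp(-k (x - x0)))` (params `a`, `c`, `k`, `x0`)
#'
#' A user-defined family passes `f` (and optionally `fprime`) directly; when no
#' closed-form derivative is registered, a central difference with step `1e-6`
#' is used.
#'
#' @param family One of `"linear"`, `"saturating"`, `"convex"`, `"sigmoid"`,
#'   `"user"`.
#' @param params Named numeric vector of family parameters (see Details).
#' @param x_hat Upper bound of competitive inferiority (domain is
#'   `[0, x_hat]`).
#' @param f,fprime For `family = "user"`: the fecundity function and,
#'   optionally, its derivative.
#'
#' @return An object of class `trade_off` with elements `family`, `params`,
#'   `x_hat`, `f`, `fprime`.
#'
#' @examples
#' to <- trade_off("linear", c(a = 1, b = 1), x_hat = 2.5)
#' tradeoff_eval(to, 0.5)   # 1.5
#' tradeoff_deriv(to, 0.5)  # 1
#' @export
trade_off <- function(family = c("linear", "saturating", "convex", "sigmoid", "user"),
                      params = NULL, x_hat = 2.5, f = NULL, fprime = NULL) {
  family <- rlang::arg_match(family)
  if (!is.numeric(x_hat) || length(x_hat) != 1L || x_hat <= 0) {
    rlang::abort("`x_hat` must be a single positive number.", class = "radlabel_parameter_error")
  }
  p <- as.list(params)

  need <- function(nms) {
    miss <- setdiff(nms, names(p))
    if (length(miss) > 0) {
      rlang::abort(
        paste0("Trade-off family '", family, "' needs parameter(s): ",
               paste(miss, collapse = ", ")),
        class = "radlabel_parameter_error"
      )
    }
  }

  if (family == "linear") {
    need(c("a", "b"))
    fn <- function(x) p$a + p$b * x
    dfn <- function(x) rep(p$b, length(x))
  } else if (family == "saturating") {
    need(c("a", "c", "k"))
    fn <- function(x) p$a + p$c * (1 - exp(-p$k * x))
    dfn <- function(x) p$c * p$k * exp(-p$k * x)
  } else if (family == "convex") {
    need(c("a", "b", "gamma"))
    if (p$gamma <= 1) {
      rlang::abort("Convex family requires gamma > 1.", class = "radlabel_parameter_error")
    }
    fn <- function(x) p$a + p$b * x^p$gamma
    dfn <- function(x) p$b * p$gamma * x^(p$gamma - 1)
  } else if (family == "sigmoid") {
    need(c("a", "c", "k", "x0"))
    fn <- function(x) p$a + p$c / (1 + exp(-p$k * (x - p$x0)))
    dfn <- function(x) {
      s <- 1 / (1 + exp(-p$k * (x - p$x0)))
      p$c * p$k * s * (1 - s)
    }
  } else {
    if (!is.function(f)) {
      rlang::abort("family = 'user' requires a function `f`.", class = "radlabel_parameter_error")
    }
    fn <- f
    dfn <- if (is.function(fprime)) fprime else NULL
  }

  if (is.null(dfn)) {
    # central difference, step 1e-6, clipped to the domain at the endpoints
    dfn <- function(x) {
      h <- 1e-6
      lo <- pmax(x - h, 0)
      hi <- pmin(x + h, x_hat)
      (fn(hi) - fn(lo)) / (hi - lo)
    }
  }

  obj <- structure(
    list(family = family, params = p, x_hat = x_hat, f = fn, fprime = dfn),
    class = "trade_off"
  )
  validate_trade_off(obj)
  obj
}

validate_trade_off <- function(to, n_check = 64L) {
  xs <- seq(0, to$x_hat, length.out = n_check)
  fx <- to$f(xs)
  if (any(!is.finite(fx)) || any(fx <= 0)) {
    rlang::abort("Trade-off must be positive and finite on [0, x_hat].",
                 class = "radlabel_parameter_error")
  }
  if (any(diff(fx) <= 0)) {
    rlang::abort("Trade-off must be strictly increasing on [0, x_hat].",
                 class = "radlabel_parameter_error")
  }
  invisible(to)
}

#' Evaluate a trade-off or its derivative
#'
#' @param to A [trade_off()] object.
#' @param x Competitive inferiority value(s) in `[0, x_hat]`.
#' @return Fecundity `f(x)` (or derivative `f'(x)`), vectorised over `x`.
#' @export
tradeoff_eval <- function(to, x) {
  stopifnot(inherits(to, "trade_off"))
  if (any(x < 0 | x > to$x_hat)) {
    rlang::abort("`x` outside the trade-off domain [0, x_hat].",
                 class = "radlabel_domain_error")
  }
  to$f(x)
}

#' @rdname tradeoff_eval
#' @export
tradeoff_deriv <- function(to, x) {
  stopifnot(inherits(to, "trade_off"))
  if (any(x < 0 | x > to$x_hat)) {
    rlang::abort("`x` outside the trade-off domain [0, x_hat].",
                 class = "radlabel_domain_error")
  }
  to$fprime(x)
}

#' @export
print.trade_off <- function(x, ...) {
  cat("<trade_off> family:", x$family, " x_hat:", x$x_hat, "\n")
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
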