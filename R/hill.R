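#' Normalized Hill activation function
#'
#' Sigmoid transfer function used on every edge of the logic-based ODE
#' network, constrained so that `f(0) = 0`, `f(EC50) = 0.5` and `f(1) = 1`.
#' The closed form is
#' \deqn{f(x) = \frac{B x^n}{K^n + x^n}, \quad
#'       B = \frac{EC_{50}^n - 1}{2 EC_{50}^n - 1}, \quad K^n = B - 1.}
#' The function is monotone increasing; for inputs above 1 (permitted only
#' for the glucose stimulus) it saturates toward `B`.
#'
#' @param x input activity, non-negative. May exceed 1.
#' @param n Hill coefficient, `>= 1`.
#' @param ec50 half-effect in (0, 1) with `2 * ec50^n != 1`.
#' @return activity of the same length as `x`.
#' @examples
#' normalized_hill(c(0, 0.5, 1))      # 0, 0.5, 1
#' @export
normalized_hill <- function(x, n = 1.4, ec50 = 0.5) {
  cst <- hill_constants(n, ec50)
  if (any(x < 0)) stop("normalized_hill(): input activity must be non-negative")
  cst$B * x^n / (cst$Kn + x^n)
}

## B and K^n for the normalized Hill form; errors when the constants are
## undefined (2 * ec50^n == 1).
hill_constants <- function(n, ec50) {
  if (any(n < 1)) stop("Hill coefficient n must be >= 1")
  if (any(ec50 <= 0 | ec50 >= 1)) stop("ec50 must lie strictly in (0, 1)")
  en <- ec50^n
  if (any(abs(2 * en - 1) < 1e-12)) {
    stop("normalized Hill constants undefined: 2 * ec50^n == 1")
  }
  B <- (en - 1) / (2 * en - 1)
  list(B = B, Kn = B - 1)
}

#' Edge transfer factor
#'
#' Activating edges pass their input through [normalized_hill()]; inhibiting
#' edges return `1 - f(x)`, so a fully active inhibitor silences its target
#' and an inactive one leaves it untouched.
#'
#' @param x input activity.
#' @param sign `"activating"` or `"inhibiting"`.
#' @inheritParams normalized_hill
#' @return transfer factor.
#' @export
edge_transfer <- function(x, sign = c("activating", "inhibiting"),
                          n = 1.4, ec50 = 0.5) {
  sign <- match.arg(sign)
  f <- normalized_hill(x, n, ec50)
  if (sign == "inhibiting") 1 - f else f
}

#' Logic-gate algebra for reaction drives
#'
#' Within one reaction the transfer factors of its inputs combine by AND
#' (product). Reactions sharing a target combine by the probabilistic OR
#' `a + b - a * b`, folded left-associatively over the target's reactions in
#' declared order. `or_fold()` expects drives already weighted and clipped to
#' \[0, 1\].
#'
#' @param factors numeric vector of per-input transfer factors.
#' @param drives numeric vector of per-reaction weighted drives in \[0, 1\].
#' @return scalar activation.
#' @export
and_combine <- function(factors) prod(factors)

#' @rdname and_combine
#' @export
or_fold <- function(drives) {
  out <- 0
  for (a in drives) out <- out + a - out * a
  out
}
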