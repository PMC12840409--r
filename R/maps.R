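#' Logistic map family
#'
#' `P(z) = r z (1 - z)` on `[0, 1]`, the standard analytic one-humped map
#' used throughout as an oracle stand-in for the empirical peak map. The
#' returned function carries its derivative `P'(z) = r (1 - 2 z)` in the
#' `"deriv"` attribute.
#'
#' @param r growth parameter in `(0, 4]`.
#' @return a function of class `map1d` with a `"deriv"` attribute.
#' @examples
#' P <- logistic_map(3.2)
#' logistic_two_cycle(3.2)  # the attracting 2-cycle
#' @export
logistic_map <- function(r) {
  check_positive(r, "r")
  f <- function(z) r * z * (1 - z)
  attr(f, "deriv") <- function(z) r * (1 - 2 * z)
  attr(f, "domain") <- c(0, 1)
  class(f) <- c("map1d", "function")
  f
}

#' Closed forms for logistic cycles
#'
#' The nontrivial fixed point `1 - 1/r`, and for `r > 3` the 2-cycle
#' `(r + 1 +- sqrt((r + 1)(r - 3))) / (2 r)` with multiplier
#' `Lambda_2 = -r^2 + 2 r + 4`.
#'
#' @param r logistic parameter.
#' @return `logistic_fixed_point`: a number. `logistic_two_cycle`: a list
#'   with `points` and `multiplier` (NULL when `r <= 3`).
#' @export
logistic_fixed_point <- function(r) 1 - 1 / r

#' @rdname logistic_fixed_point
#' @export
logistic_two_cycle <- function(r) {
  if (r <= 3) return(NULL)
  s <- sqrt((r + 1) * (r - 3))
  list(points = sort(c((r + 1 + s) / (2 * r), (r + 1 - s) / (2 * r))),
       multiplier = -r^2 + 2 * r + 4)
}

#' Iterate a 1D map
#'
#' @param P a map function.
#' @param z0 initial point.
#' @param n number of iterates to return.
#' @param burn_in iterates discarded first.
#' @return numeric vector of `n` iterates.
#' @export
iterate_map <- function(P, z0, n, burn_in = 0) {
  z <- z0
  for (k in seq_len(burn_in)) z <- P(z)
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- z
    z <- P(z)
  }
  out
}

# derivative evaluator for a 1D map: analytic if attached, else central
# finite difference
map_deriv <- function(P, deriv = NULL, fd_h = 1e-6) {
  if (is.null(deriv)) deriv <- attr(P, "deriv")
  if (is.null(deriv)) {
    deriv <- function(z) (P(z + fd_h) - P(z - fd_h)) / (2 * fd_h)
  }
  deriv
}
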