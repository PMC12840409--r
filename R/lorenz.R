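#' Lorenz system parameters
#'
#' Container for the three positive parameters of the Lorenz vector field
#' \deqn{\dot x = \sigma(y - x),\quad \dot y = x(\rho - z) - y,\quad
#'       \dot z = xy - \beta z.}
#' The classical chaotic regime uses `sigma = 10`, `rho = 28`, `beta = 8/3`.
#'
#' @param sigma,rho,beta strictly positive reals.
#' @return an object of class `lorenz_params`.
#' @examples
#' p <- lorenz_params()
#' lorenz_field(c(1, 1, 1), p)
#' @export
lorenz_params <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  for (v in list(sigma = sigma, rho = rho, beta = beta)) check_positive(v, "lorenz parameter")
  structure(list(sigma = sigma, rho = rho, beta = beta), class = "lorenz_params")
}

#' @export
print.lorenz_params <- function(x, ...) {
  cat(sprintf("Lorenz parameters: sigma = %g, rho = %g, beta = %g\n",
              x$sigma, x$rho, x$beta))
  invisible(x)
}

#' Lorenz vector field
#'
#' Time derivative of the Lorenz system at a phase-space point.
#'
#' @param state numeric length-3 vector `(x, y, z)`.
#' @param params a [lorenz_params()] object.
#' @return numeric length-3 derivative vector.
#' @export
lorenz_field <- function(state, params = lorenz_params()) {
  check_finite(state, "state")
  c(params$sigma * (state[2] - state[1]),
    state[1] * (params$rho - state[3]) - state[2],
    state[1] * state[2] - params$beta * state[3])
}

#' Jacobian of the Lorenz vector field
#'
#' @inheritParams lorenz_field
#' @return a 3x3 numeric matrix.
#' @export
lorenz_jacobian <- function(state, params = lorenz_params()) {
  check_finite(state, "state")
  matrix(c(-params$sigma,            params$sigma, 0,
           params$rho - state[3],   -1,           -state[1],
           state[2],                 state[1],    -params$beta),
         nrow = 3, byrow = TRUE)
}

#' Equilibria of the Lorenz flow
#'
#' The origin, and for `rho > 1` the symmetric pair
#' `C+- = (+-sqrt(beta(rho-1)), +-sqrt(beta(rho-1)), rho-1)`.
#'
#' @param params a [lorenz_params()] object.
#' @return a matrix with one equilibrium per row.
#' @export
lorenz_equilibria <- function(params = lorenz_params()) {
  eq <- matrix(0, nrow = 1, ncol = 3)
  if (params$rho > 1) {
    r <- sqrt(params$beta * (params$rho - 1))
    eq <- rbind(eq, c(r, r, params$rho - 1), c(-r, -r, params$rho - 1))
  }
  colnames(eq) <- c("x", "y", "z")
  eq
}

#' One explicit-Euler step of the discrete Lorenz map
#'
#' The explicit time-h map `T(X_k) = X_k + h F(X_k)` obtained by Euler
#' discretization of the Lorenz field; identical to
#' `step_explicit(state, h, field, "euler")` with the Lorenz field.
#'
#' @param state numeric length-3 vector.
#' @param h positive step.
#' @param params a [lorenz_params()] object.
#' @return the next state.
#' @export
discrete_lorenz_step <- function(state, h, params = lorenz_params()) {
  check_positive(h, "h")
  state + h * lorenz_field(state, params)
}
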