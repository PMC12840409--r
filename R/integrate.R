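#' Time-discretization scheme specification
#'
#' Three one-step schemes are supported: explicit Euler (order 1), the
#' implicit midpoint rule solved by fixed-point iteration (order 2), and the
#' classical four-stage Runge-Kutta method (order 4). `tol` and `max_iter`
#' only apply to the implicit midpoint scheme, whose inner iteration
#' \deqn{X_{k+1}^{(n+1)} = X_k + h F\left(\frac{X_k + X_{k+1}^{(n)}}{2}\right)}
#' is stopped when the max-norm difference of consecutive iterates falls
#' below `tol`.
#'
#' @param name one of `"euler"`, `"rk4"`, `"midpoint_implicit"`.
#' @param tol positive fixed-point stopping threshold (midpoint only).
#' @param max_iter positive integer iteration cap (midpoint only).
#' @return an object of class `scheme_spec` with fields `name`, `order`,
#'   `tol`, `max_iter`.
#' @export
scheme_spec <- function(name = c("rk4", "euler", "midpoint_implicit"),
                        tol = 1e-12, max_iter = 50L) {
  name <- match.arg(name)
  check_positive(tol, "tol")
  if (max_iter < 1) pk_stop("max_iter must be >= 1", "peaknet_invalid")
  order <- switch(name, euler = 1L, midpoint_implicit = 2L, rk4 = 4L)
  structure(list(name = name, order = order, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "scheme_spec")
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "scheme_spec")) scheme else scheme_spec(scheme)
}

#' One explicit integration step
#'
#' Euler: `X + h F(X)`. RK4: the four-stage combination
#' `X + h/6 (k1 + 2 k2 + 2 k3 + k4)`.
#'
#' @param state numeric state vector.
#' @param h positive step size.
#' @param field function `state -> derivative` of the same dimension.
#' @param scheme `"euler"` or `"rk4"` (name or [scheme_spec()]).
#' @return the next state.
#' @export
step_explicit <- function(state, h, field, scheme = "rk4") {
  scheme <- as_scheme(scheme)
  check_positive(h, "h")
  if (scheme$name == "euler") {
    out <- state + h * field(state)
    if (any(!is.finite(out))) {
      pk_stop("non-finite state after euler step", "peaknet_step_failure")
    }
    return(out)
  }
  if (scheme$name != "rk4") {
    pk_stop("step_explicit supports euler and rk4 only", "peaknet_invalid")
  }
  k1 <- field(state)
  k2 <- field(state + h / 2 * k1)
  k3 <- field(state + h / 2 * k2)
  k4 <- field(state + h * k3)
  stages <- c(k1, k2, k3, k4)
  if (any(!is.finite(stages))) {
    cond <- errorCondition("non-finite intermediate stage in rk4 step",
                           class = c("peaknet_step_failure", "peaknet_error"))
    cond$stages <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
    stop(cond)
  }
  out <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    pk_stop("non-finite state after rk4 step", "peaknet_step_failure")
  }
  out
}

#' One implicit-midpoint step via fixed-point iteration
#'
#' Solves `X_{k+1} = X_k + h F((X_k + X_{k+1}) / 2)` by the iteration seeded
#' with `X_{k+1}^(0) = X_k`, stopping when the max-norm update falls below
#' `tol`. The iteration is a contraction when `h L / 2 < 1` for a field with
#' Lipschitz constant `L`; outside that regime non-convergence is signalled.
#'
#' @inheritParams step_explicit
#' @param tol positive stopping threshold on the sup-norm update.
#' @param max_iter iteration cap; exceeding it raises a
#'   `peaknet_no_convergence` error.
#' @return a list with `state` (the fixed point) and `iterations`.
#' @export
step_midpoint_implicit <- function(state, h, field, tol = 1e-12, max_iter = 50L) {
  check_positive(h, "h")
  check_positive(tol, "tol")
  x_next <- state
  for (n in seq_len(max_iter)) {
    x_new <- state + h * field((state + x_next) / 2)
    if (any(!is.finite(x_new))) {
      pk_stop("non-finite iterate in midpoint step", "peaknet_step_failure")
    }
    delta <- max_norm(x_new - x_next)
    x_next <- x_new
    if (delta <= tol) {
      return(list(state = x_next, iterations = n))
    }
  }
  pk_stop(sprintf("midpoint fixed-point iteration did not reach tol = %g in %d iterations (contraction requires h L / 2 < 1)",
                  tol, max_iter),
          "peaknet_no_convergence")
}

step_once <- function(state, h, field, scheme) {
  if (scheme$name == "midpoint_implicit") {
    step_midpoint_implicit(state, h, field, scheme$tol, scheme$max_iter)$state
  } else {
    step_explicit(state, h, field, scheme)
  }
}

#' Integrate a vector field on a uniform time grid
#'
#' Produces the discrete trajectory `{X_k}` with `X_{k+1}` obtained from
#' `X_k` by the chosen one-step scheme. The result is deterministic: the
#' same inputs give bit-identical trajectories. Integration is aborted (with
#' the failing step index attached) if any coordinate exceeds `guard` in
#' absolute value, since bounded attractors make such growth a scheme
#' failure rather than genuine dynamics.
#'
#' @param x0 numeric initial state (any dimension).
#' @param field function `state -> derivative`.
#' @param h positive step.
#' @param n_steps number of steps (`N >= 1`); the trajectory has `N + 1`
#'   states.
#' @param scheme scheme name or [scheme_spec()].
#' @param t0 initial time.
#' @param params optional parameter object stored for provenance.
#' @param guard divergence guard on `max |coordinate|`.
#' @return an object of class `trajectory`: a list with `t0`, `h`, `states`
#'   (an `(N+1) x d` matrix), `scheme`, and `params`.
#' @examples
#' tr <- integrate_system(c(1, 1, 1), function(s) lorenz_field(s),
#'                        h = 0.01, n_steps = 100)
#' dim(tr$states)
#' @export
integrate_system <- function(x0, field, h, n_steps, scheme = "rk4",
                             t0 = 0, params = NULL, guard = 1e6) {
  scheme <- as_scheme(scheme)
  check_finite(x0, "x0")
  check_positive(h, "h")
  if (n_steps < 1) pk_stop("n_steps must be >= 1", "peaknet_invalid")
  d <- length(x0)
  states <- matrix(NA_real_, nrow = n_steps + 1L, ncol = d)
  states[1L, ] <- x0
  x <- x0
  for (k in seq_len(n_steps)) {
    x <- tryCatch(step_once(x, h, field, scheme), error = function(e) {
      e$step_index <- k
      e$message <- sprintf("%s (at step %d)", conditionMessage(e), k)
      stop(e)
    })
    if (max(abs(x)) > guard) {
      cond <- errorCondition(
        sprintf("trajectory escaped the divergence guard |coord| > %g at step %d", guard, k),
        class = c("peaknet_step_failure", "peaknet_error"))
      cond$step_index <- k
      stop(cond)
    }
    states[k + 1L, ] <- x
  }
  colnames(states) <- if (d == 3L) c("x", "y", "z") else paste0("s", seq_len(d) - 1L)
  structure(list(t0 = t0, h = h, states = states, scheme = scheme,
                 params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Discrete trajectory: %d states, dim %d, h = %g, scheme = %s\n",
              nrow(x$states), ncol(x$states), x$h, x$scheme$name))
  invisible(x)
}

#' Time stamps of a trajectory
#'
#' @param traj a `trajectory` object.
#' @return numeric vector `t0 + k h`.
#' @export
trajectory_times <- function(traj) {
  traj$t0 + (seq_len(nrow(traj$states)) - 1L) * traj$h
}

#' Linear stability gain of a one-step scheme
#'
#' For the scalar test equation `x' = lambda x` each scheme reduces to
#' `x_{k+1} = R(z) x_k` with `z = h lambda`:
#' Euler `R(z) = 1 + z`; RK4 `R(z) = 1 + z + z^2/2 + z^3/6 + z^4/24`;
#' implicit midpoint `R(z) = (1 + z/2) / (1 - z/2)` (A-stable).
#'
#' @param z complex (or real) argument; vectorized.
#' @param scheme scheme name or [scheme_spec()].
#' @return complex gain values.
#' @export
stability_gain <- function(z, scheme = "rk4") {
  scheme <- as_scheme(scheme)
  if (anyNA(z) || any(!is.finite(Mod(z)))) {
    pk_stop("z must be finite", "peaknet_nonfinite")
  }
  z <- as.complex(z)
  switch(scheme$name,
         euler = 1 + z,
         rk4 = 1 + z + z^2 / 2 + z^3 / 6 + z^4 / 24,
         midpoint_implicit = {
           if (any(Mod(z - 2) < 1e-14)) {
             pk_stop("midpoint gain has a pole at z = 2", "peaknet_degenerate")
           }
           (1 + z / 2) / (1 - z / 2)
         })
}

#' Recommend a step size from sampling and accuracy criteria
#'
#' Criterion A resolves the oscillation: `h <= min_n(t_{n+1} - t_n) / M`
#' with `M` samples per inter-peak interval. Criterion B bounds the global
#' error of an order-`p` scheme: `h <= C tau^{1/p}` for target accuracy
#' `tau`. The recommended step is the minimum of the two.
#'
#' @param min_spacing smallest observed inter-peak time.
#' @param M samples per inter-peak interval (`>= 2`).
#' @param tau target accuracy for the peak heights.
#' @param C order-dependent constant of criterion B.
#' @param p integrator order.
#' @return a list with `criterion_a`, `criterion_b`, and `h` (their minimum).
#' @export
recommend_step <- function(min_spacing, M, tau, C = 1, p = 4) {
  check_positive(c(min_spacing, tau, C, p), "recommend_step inputs")
  if (M < 2) pk_stop("M must be >= 2", "peaknet_invalid")
  a <- min_spacing / M
  b <- C * tau^(1 / p)
  list(criterion_a = a, criterion_b = b, h = min(a, b))
}

#' Adaptive step-control configuration
#'
#' Parameters for the step-doubling controller: target accuracy `tau`,
#' scheme order `p`, initial and bracketing steps, and the per-step growth
#' cap that guards the update `h (tau / eps)^{1/(p+1)}` against a division
#' blow-up when the estimated error `eps` is near zero.
#'
#' @param tau positive target accuracy.
#' @param p integrator order.
#' @param h0,h_min,h_max positive steps with `h_min <= h0 <= h_max`.
#' @param growth_cap maximal per-step growth factor (> 1).
#' @return an object of class `adaptive_config`.
#' @export
adaptive_config <- function(tau = 1e-6, p = 4, h0 = 0.01,
                            h_min = 1e-6, h_max = 0.1, growth_cap = 5) {
  check_positive(c(tau, h0, h_min, h_max), "adaptive_config inputs")
  if (growth_cap <= 1) pk_stop("growth_cap must be > 1", "peaknet_invalid")
  if (!(h_min <= h0 && h0 <= h_max)) {
    pk_stop("need h_min <= h0 <= h_max", "peaknet_invalid")
  }
  structure(list(tau = tau, p = p, h0 = h0, h_min = h_min, h_max = h_max,
                 growth_cap = growth_cap),
            class = "adaptive_config")
}

#' One adaptive step with step-doubling error control
#'
#' Advances the state by one full step and by two half steps with the same
#' scheme; their max-norm difference `eps_n` estimates the local error. The
#' proposed next step is `h (tau / eps_n)^{1/(p+1)}`, clipped to
#' `[h_min, h_max]` and to at most `growth_cap * h`. The (more accurate)
#' two-half-step state is the accepted state when `eps_n <= tau`.
#'
#' @param state numeric state vector.
#' @param h current step, inside `[cfg$h_min, cfg$h_max]`.
#' @param field function `state -> derivative`.
#' @param scheme scheme name or [scheme_spec()]; its order is used as `p`.
#' @param cfg an [adaptive_config()].
#' @return a list with `state` (two-half-step result), `accepted`
#'   (`eps_n <= tau`), `h_next`, and `eps`.
#' @export
adaptive_step <- function(state, h, field, scheme = "rk4", cfg = adaptive_config()) {
  scheme <- as_scheme(scheme)
  if (h < cfg$h_min || h > cfg$h_max) {
    pk_stop("h outside [h_min, h_max]", "peaknet_invalid")
  }
  full <- step_once(state, h, field, scheme)
  half <- step_once(step_once(state, h / 2, field, scheme), h / 2, field, scheme)
  eps <- max_norm(full - half)
  if (!is.finite(eps)) pk_stop("non-finite step-doubling error", "peaknet_step_failure")
  p <- scheme$order
  ratio <- if (eps == 0) Inf else (cfg$tau / eps)^(1 / (p + 1))
  h_next <- h * min(ratio, cfg$growth_cap)
  h_next <- min(max(h_next, cfg$h_min), cfg$h_max)
  list(state = half, accepted = eps <= cfg$tau, h_next = h_next, eps = eps)
}

#' Advance one accepted step under adaptive control
#'
#' Wraps [adaptive_step()] in a rejection loop: a rejected proposal is
#' retried at the controller's step scaled by the standard backoff factor
#' 0.9 (the raw controller lands exactly on the acceptance boundary, where
#' a small safety margin is needed for progress). Errors if the step
#' reaches `h_min` without acceptance.
#'
#' @inheritParams adaptive_step
#' @param max_retries retry cap.
#' @return the accepted [adaptive_step()] result plus a `retries` count.
#' @export
adaptive_advance <- function(state, h, field, scheme = "rk4",
                             cfg = adaptive_config(), max_retries = 20L) {
  retries <- 0L
  repeat {
    st <- adaptive_step(state, h, field, scheme, cfg)
    if (st$accepted) {
      st$retries <- retries
      return(st)
    }
    if (h <= cfg$h_min || retries >= max_retries) {
      pk_stop("adaptive controller could not meet tau before h_min", "peaknet_step_failure")
    }
    h <- max(cfg$h_min, 0.9 * st$h_next)
    retries <- retries + 1L
  }
}
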