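#' Lyapunov spectrum container
#'
#' Exponents sorted descending, either per map step (`per_step`) or per
#' unit time (`per_time`). Natural logarithms throughout.
#'
#' @param exponents numeric vector (will be sorted descending).
#' @param units `"per_step"` or `"per_time"`.
#' @param h step size used (required for `per_step` spectra that are to be
#'   rescaled to continuous time).
#' @param n_steps,burn_in bookkeeping counts.
#' @return an object of class `lyapunov_spectrum`.
#' @export
lyapunov_spectrum <- function(exponents, units = c("per_step", "per_time"),
                              h = NA_real_, n_steps = NA_integer_,
                              burn_in = NA_integer_) {
  units <- match.arg(units)
  exponents <- sort(exponents, decreasing = TRUE)
  structure(list(exponents = exponents, units = units, h = h,
                 n_steps = n_steps, burn_in = burn_in),
            class = "lyapunov_spectrum")
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  cat(sprintf("Lyapunov spectrum (%s): %s\n", x$units,
              paste(format(x$exponents, digits = 5), collapse = ", ")))
  invisible(x)
}

#' Lyapunov spectrum of a discrete map
#'
#' QR-based tangent propagation along the orbit of a map: the tangent frame
#' is multiplied by the Jacobian at each iterate and re-orthonormalized by
#' QR; exponents are the time averages of `log |diag R|`. For a 1D map this
#' reduces exactly to the Birkhoff average
#' \deqn{\lambda_{\max} = \lim_{n\to\infty}\frac1n\sum_{k=0}^{n-1}
#'   \log|P'(z_k)|.}
#' A singular Jacobian encountered along the orbit yields a `-Inf`
#' sentinel exponent.
#'
#' @param map function `x -> x_next` (scalar or vector state).
#' @param jacobian function `x -> J` (scalar derivative in 1D).
#' @param x0 initial state.
#' @param n number of post-burn-in iterations (`>= 100`).
#' @param burn_in iterations discarded first.
#' @return a [lyapunov_spectrum()] with units `per_step`.
#' @examples
#' P <- logistic_map(4)
#' lyapunov_map(P, attr(P, "deriv"), 0.3, n = 1000)  # ~ log(2)
#' @export
lyapunov_map <- function(map, jacobian, x0, n, burn_in = 0L) {
  if (n < 100) pk_stop("need n >= 100 post burn-in", "peaknet_invalid")
  x <- x0
  for (k in seq_len(burn_in)) x <- map(x)
  d <- length(x0)
  if (d == 1L) {
    s <- 0
    for (k in seq_len(n)) {
      dp <- abs(jacobian(x))
      s <- s + if (dp == 0) -Inf else log(dp)
      x <- map(x)
    }
    return(lyapunov_spectrum(s / n, "per_step", n_steps = n, burn_in = burn_in))
  }
  Q <- diag(d)
  sums <- numeric(d)
  for (k in seq_len(n)) {
    A <- jacobian(x) %*% Q
    qrA <- qr(A)
    Q <- qr.Q(qrA)
    rdiag <- diag(qr.R(qrA))
    # fix signs so Q stays right-handed and R has meaningful diagonal
    sgn <- sign(rdiag); sgn[sgn == 0] <- 1
    Q <- Q * rep(sgn, each = d)
    ar <- abs(rdiag)
    sums <- sums + ifelse(ar == 0, -Inf, log(ar))
    x <- map(x)
  }
  lyapunov_spectrum(sums / n, "per_step", n_steps = n, burn_in = burn_in)
}

#' Lyapunov spectrum of a flow
#'
#' Integrates the tangent (variational) flow `dQ/dt = J(x(t)) Q` alongside
#' the trajectory with the same RK4 step, re-orthonormalizing the frame by
#' QR every `qr_every` steps and accumulating `log |diag R|`. Exponents are
#' reported per unit time. For the Lorenz flow at classical parameters the
#' expected signature is `lambda_1 > 0`, `lambda_2 ~ 0`, `lambda_3 < 0`,
#' with the sum equal to the constant field divergence
#' `-(sigma + 1 + beta)`.
#'
#' @param field function `x -> dx/dt`.
#' @param jacobian function `x -> d x d` Jacobian of the field.
#' @param x0 initial state.
#' @param h integration step.
#' @param t_total averaging time (after burn-in).
#' @param burn_in transient time discarded before averaging.
#' @param qr_every re-orthonormalization interval in steps.
#' @param guard divergence guard; escape aborts with diagnostics.
#' @return a [lyapunov_spectrum()] with units `per_time` and recorded `h`.
#' @export
lyapunov_flow <- function(field, jacobian, x0, h, t_total, burn_in = 0,
                          qr_every = 10L, guard = 1e6) {
  check_positive(h, "h")
  d <- length(x0)
  x <- x0
  n_burn <- round(burn_in / h)
  for (k in seq_len(n_burn)) {
    x <- rk4_state(x, h, field)
    if (max(abs(x)) > guard) {
      pk_stop(sprintf("trajectory escaped during burn-in at step %d", k),
              "peaknet_step_failure")
    }
  }
  n <- round(t_total / h)
  Q <- diag(d)
  sums <- numeric(d)
  for (k in seq_len(n)) {
    st <- rk4_tangent(x, Q, h, field, jacobian)
    x <- st$x; Q <- st$Q
    if (max(abs(x)) > guard) {
      pk_stop(sprintf("trajectory escaped at step %d of the averaging window", k),
              "peaknet_step_failure")
    }
    if (k %% qr_every == 0L || k == n) {
      qrQ <- qr(Q)
      rdiag <- diag(qr.R(qrQ))
      Q <- qr.Q(qrQ)
      sgn <- sign(rdiag); sgn[sgn == 0] <- 1
      Q <- Q * rep(sgn, each = d)
      sums <- sums + log(abs(rdiag))
    }
  }
  lyapunov_spectrum(sums / (n * h), "per_time", h = h, n_steps = n,
                    burn_in = as.integer(n_burn))
}

# one rk4 step of the state alone
rk4_state <- function(x, h, field) {
  k1 <- field(x)
  k2 <- field(x + h / 2 * k1)
  k3 <- field(x + h / 2 * k2)
  k4 <- field(x + h * k3)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# one rk4 step of state + tangent frame for dQ/dt = J(x) Q
rk4_tangent <- function(x, Q, h, field, jacobian) {
  k1 <- field(x);               K1 <- jacobian(x) %*% Q
  x2 <- x + h / 2 * k1
  k2 <- field(x2);              K2 <- jacobian(x2) %*% (Q + h / 2 * K1)
  x3 <- x + h / 2 * k2
  k3 <- field(x3);              K3 <- jacobian(x3) %*% (Q + h / 2 * K2)
  x4 <- x + h * k3
  k4 <- field(x4);              K4 <- jacobian(x4) %*% (Q + h * K3)
  list(x = x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4),
       Q = Q + h / 6 * (K1 + 2 * K2 + 2 * K3 + K4))
}

#' Convert a per-step spectrum to per unit time (and back)
#'
#' Discrete and continuous exponents are related by
#' `lambda_disc = h * Lambda_cont + O(h^2)`, so the per-time spectrum is
#' obtained by dividing each exponent by the recorded step `h`.
#'
#' @param spec a [lyapunov_spectrum()].
#' @param h step; defaults to the one recorded in `spec`.
#' @param to target units.
#' @return a rescaled [lyapunov_spectrum()].
#' @export
scale_exponents <- function(spec, h = spec$h, to = c("per_time", "per_step")) {
  to <- match.arg(to)
  if (is.na(h)) pk_stop("no step h recorded; cannot rescale", "peaknet_invalid")
  if (spec$units == to) return(spec)
  factor <- if (to == "per_time") 1 / h else h
  lyapunov_spectrum(spec$exponents * factor, to, h = h,
                    n_steps = spec$n_steps, burn_in = spec$burn_in)
}

#' Kaplan-Yorke dimension from a Lyapunov spectrum
#'
#' \deqn{D_{KY} = j + \frac{\sum_{i \le j} \lambda_i}{|\lambda_{j+1}|},}
#' where `j` is the largest index with non-negative partial sum. `D = 0`
#' when already `lambda_1 < 0`; `D` equals the phase-space dimension when
#' every partial sum is non-negative.
#'
#' @param spec a [lyapunov_spectrum()] or a sorted-descending numeric
#'   vector.
#' @return the dimension estimate (a single number).
#' @examples
#' kaplan_yorke(c(0.906, 0, -14.572))
#' @export
kaplan_yorke <- function(spec) {
  lam <- if (inherits(spec, "lyapunov_spectrum")) spec$exponents else sort(spec, decreasing = TRUE)
  cs <- cumsum(lam)
  if (cs[1] < 0) return(0)
  if (all(cs >= 0)) return(length(lam))
  j <- max(which(cs >= 0))
  nxt <- lam[j + 1]
  if (nxt == 0) pk_stop("lambda_{j+1} = 0 at the pivot; dimension undefined",
                        "peaknet_degenerate")
  j + cs[j] / abs(nxt)
}
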