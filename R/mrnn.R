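#' Continuous-state recurrent operator (MRNN)
#'
#' The m-dimensional smooth recursion
#' \deqn{x_{n+1} = (1-\gamma)\,x_n + \eta\, W \tanh(x_n) + b,}
#' with recurrent matrix `W` drawn from a seeded standard-normal ensemble
#' and rescaled to spectral radius 1, gain `eta > 0`, dissipation
#' `gamma` in `(0, 1]`, and a unit-norm scalar readout
#' `y = c' x + d`. `eta` and `gamma` are the control parameters that move
#' the operator through the fixed-point / periodic / chaotic hierarchy.
#'
#' @param m state dimension (default 64).
#' @param eta nonlinear gain (> 0).
#' @param gamma dissipation in (0, 1].
#' @param seed RNG seed; a degenerate draw (numerically zero spectral
#'   radius) is redrawn from an incremented sub-seed and logged in the
#'   `redraws` field.
#' @param bias_scale standard deviation of the bias draw (default 0).
#' @return an object of class `mrnn_params` with fields `m`, `W`, `b`,
#'   `eta`, `gamma`, `c`, `d`, `seed`, `redraws`.
#' @examples
#' p <- mrnn_init(8, eta = 0.9, gamma = 0.25, seed = 1)
#' spectral_radius(p$W)  # 1 up to normalization error
#' @export
mrnn_init <- function(m = 64L, eta = 0.9, gamma = 0.25, seed = 1L,
                      bias_scale = 0) {
  if (m < 1) pk_stop("m must be >= 1", "peaknet_invalid")
  check_positive(eta, "eta")
  if (gamma <= 0 || gamma > 1) pk_stop("gamma must lie in (0, 1]", "peaknet_invalid")
  redraws <- 0L
  repeat {
    set.seed(seed + redraws)
    W <- matrix(stats::rnorm(m * m), m, m)
    rho <- spectral_radius(W)
    if (rho > 1e-12) break
    redraws <- redraws + 1L
    if (redraws > 10L) pk_stop("could not draw a non-degenerate W", "peaknet_degenerate")
  }
  W <- W / rho
  cvec <- stats::rnorm(m)
  cvec <- cvec / sqrt(sum(cvec^2))
  b <- if (bias_scale > 0) stats::rnorm(m, sd = bias_scale) else numeric(m)
  structure(list(m = as.integer(m), W = W, b = b, eta = eta, gamma = gamma,
                 c = cvec, d = 0, seed = as.integer(seed), redraws = redraws),
            class = "mrnn_params")
}

#' @export
print.mrnn_params <- function(x, ...) {
  cat(sprintf("MRNN: m = %d, eta = %g, gamma = %g, rho(W) = %.6f\n",
              x$m, x$eta, x$gamma, spectral_radius(x$W)))
  invisible(x)
}

#' One step of the recurrent operator
#'
#' @param x state vector of length `m`.
#' @param params an [mrnn_init()] object.
#' @return the next state.
#' @export
mrnn_step <- function(x, params) {
  out <- (1 - params$gamma) * x + params$eta * as.numeric(params$W %*% tanh(x)) + params$b
  if (any(!is.finite(out))) pk_stop("non-finite MRNN state", "peaknet_step_failure")
  out
}

#' Jacobian of the recurrent operator
#'
#' `J(x) = (1 - gamma) I + eta W diag(1 - tanh(x)^2)`; at the origin this is
#' `(1 - gamma) I + eta W`, and for saturated coordinates the corresponding
#' columns of `W` drop out.
#'
#' @inheritParams mrnn_step
#' @return an `m x m` matrix.
#' @export
mrnn_jacobian <- function(x, params) {
  check_finite(x, "x")
  phi_p <- 1 - tanh(x)^2
  (1 - params$gamma) * diag(params$m) +
    params$eta * params$W * rep(phi_p, each = params$m)
}

#' Free-run the operator
#'
#' @param params an [mrnn_init()] object.
#' @param n steps recorded (after burn-in).
#' @param x0 initial state; default a small seeded random state (the origin
#'   is a fixed point when `b = 0`).
#' @param burn_in transient steps discarded.
#' @return an `n x m` state matrix.
#' @export
mrnn_run <- function(params, n, x0 = NULL, burn_in = 0L) {
  if (is.null(x0)) {
    set.seed(params$seed + 1000L)
    x0 <- stats::rnorm(params$m, sd = 0.1)
  }
  x <- x0
  for (k in seq_len(burn_in)) x <- mrnn_step(x, params)
  out <- matrix(NA_real_, n, params$m)
  for (k in seq_len(n)) {
    out[k, ] <- x
    x <- mrnn_step(x, params)
  }
  out
}

#' Readout of a state sequence
#'
#' @param states state matrix (rows = time).
#' @param params an [mrnn_init()] object.
#' @return numeric vector `c' x + d`.
#' @export
mrnn_readout <- function(states, params) {
  as.numeric(states %*% params$c) + params$d
}

#' Monodromy matrix of a periodic orbit
#'
#' For a numerically closed T-orbit `x_0 .. x_{T-1}` the monodromy matrix
#' is the ordered Jacobian product
#' \deqn{M_T = J(x_{T-1}) \cdots J(x_1) J(x_0)} (latest factor leftmost);
#' its spectral radius `rho(M_T)` plays exactly the role of the 1D cycle
#' multiplier `|Lambda_T|`: the orbit is asymptotically stable iff
#' `rho(M_T) < 1`. For `T = 1` the monodromy matrix is the Jacobian at the
#' fixed point.
#'
#' @param orbit matrix with the orbit states as rows (`T x m`), ordered in
#'   time.
#' @param params an [mrnn_init()] object (used for both the step map and
#'   the Jacobian unless overridden).
#' @param jacobian optional function `x -> J` replacing the MRNN Jacobian.
#' @param map optional function `x -> x_next` used for the closure check.
#' @param tol closure tolerance on `||F(x_{T-1}) - x_0||`.
#' @return a list of class `monodromy_result` with `period`, `M`,
#'   `eigenvalues`, `spectral_radius`, `label`.
#' @export
monodromy <- function(orbit, params = NULL, jacobian = NULL, map = NULL,
                      tol = 1e-6) {
  if (is.null(dim(orbit))) orbit <- matrix(orbit, nrow = length(orbit))
  T <- nrow(orbit)
  if (is.null(jacobian)) jacobian <- function(x) mrnn_jacobian(x, params)
  if (is.null(map) && !is.null(params)) map <- function(x) mrnn_step(x, params)
  if (!is.null(map)) {
    gap <- max_norm(map(orbit[T, ]) - orbit[1, ])
    if (gap > tol) {
      cond <- errorCondition(
        sprintf("orbit is not closed: ||F(x_{T-1}) - x_0|| = %g > tol = %g", gap, tol),
        class = c("peaknet_invalid", "peaknet_error"))
      cond$gap <- gap
      stop(cond)
    }
  }
  M <- jacobian(orbit[1, ])
  if (T > 1) for (j in 2:T) M <- jacobian(orbit[j, ]) %*% M
  ev <- eigen(M, only.values = TRUE)$values
  rho <- max(Mod(ev))
  structure(list(period = T, M = M, eigenvalues = ev, spectral_radius = rho,
                 label = classify_stability(rho)),
            class = "monodromy_result")
}

#' @export
print.monodromy_result <- function(x, ...) {
  cat(sprintf("Monodromy: T = %d, rho(M_T) = %.6g -> %s\n",
              x$period, x$spectral_radius, x$label))
  invisible(x)
}

#' Gelfand estimate of a spectral radius
#'
#' Estimates `lim ||M^k||^{1/k}` (Frobenius norm) from the tail growth
#' `(||M^k|| / ||M^{k/2}||)^{2/k}`, which cancels the norm's transient
#' prefactor and serves as an independent cross-check of the eigenvalue
#' route.
#'
#' @param M square matrix.
#' @param k power.
#' @return a single number.
#' @export
gelfand_radius <- function(M, k = 50L) {
  P <- diag(nrow(M))
  scale_log <- 0
  half <- k %/% 2L
  log_half <- NA_real_
  for (i in seq_len(k)) {
    P <- P %*% M
    nf <- sqrt(sum(P^2))
    # renormalize to avoid overflow/underflow, tracking the log scale
    P <- P / nf
    scale_log <- scale_log + log(nf)
    if (i == half) log_half <- scale_log
  }
  exp((scale_log - log_half) / (k - half))
}
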