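#' Least-squares readout fit
#'
#' Exact minimizer of `sum_n (c' x_n + d - target_n)^2` over the readout
#' `(c, d)`. A rank-deficient design (e.g. all states identical) falls back
#' to the minimum-norm solution via the pseudoinverse and is flagged.
#'
#' @param states state matrix (rows = time, `>= m + 1` rows).
#' @param targets numeric target vector.
#' @return a list with `c`, `d`, `residual` (root-mean-square), and
#'   `rank_deficient`.
#' @export
fit_readout <- function(states, targets) {
  n <- nrow(states)
  m <- ncol(states)
  if (n < m + 1L) pk_stop("need at least m + 1 state/target pairs",
                          "peaknet_insufficient_data")
  X <- cbind(states, 1)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  rank_deficient <- sum(keep) < ncol(X)
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], targets)) / sv$d[keep])
  fitted <- as.numeric(X %*% coef)
  list(c = as.numeric(coef[seq_len(m)]), d = coef[m + 1L],
       residual = sqrt(mean((fitted - targets)^2)),
       rank_deficient = rank_deficient)
}

#' Mean one-step emulation error against a 1D target map
#'
#' Free-runs the operator, reads out `y_n = c' x_n + d`, and measures
#' \deqn{E = \frac{1}{T}\sum_n |P(y_n) - y_{n+1}|,}
#' the mean absolute discrepancy between the target map applied to the
#' readout and the next-step readout. Readout values outside the map's
#' domain are clipped to it and flagged.
#'
#' @param params an [mrnn_init()] object (with a fitted readout for a
#'   meaningful error).
#' @param P target 1D map.
#' @param T_eval evaluation steps (>= 1).
#' @param burn_in transient steps discarded.
#' @param x0 optional initial state.
#' @return a list with `E`, `clipped` (fraction of clipped readouts).
#' @export
emulation_error <- function(params, P, T_eval, burn_in = 200L, x0 = NULL) {
  if (T_eval < 1) pk_stop("T_eval must be >= 1", "peaknet_invalid")
  states <- mrnn_run(params, T_eval + 1L, x0 = x0, burn_in = burn_in)
  y <- mrnn_readout(states, params)
  dom <- attr(P, "domain")
  clipped <- 0
  y_in <- y[seq_len(T_eval)]
  if (!is.null(dom)) {
    out_of_dom <- y_in < dom[1] | y_in > dom[2]
    clipped <- mean(out_of_dom)
    y_in <- pmin(pmax(y_in, dom[1]), dom[2])
  }
  Py <- vapply(y_in, P, numeric(1))
  list(E = mean(abs(Py - y[-1L])), clipped = clipped)
}

#' Self-consistent readout fit against a 1D map
#'
#' Iterates the readout regression: given the current readout `y_n`, the
#' next-state targets are `P(y_n)` and `(c, d)` is refitted by least
#' squares on `(x_{n+1}, P(y_n))`; the norm of `c` is restored to 1 after
#' each pass. A few passes suffice for the fixed point of this
#' self-consistency loop.
#'
#' @param params an [mrnn_init()] object.
#' @param P target 1D map.
#' @param n_steps trajectory length used for fitting.
#' @param burn_in transient discarded.
#' @param passes number of refit passes.
#' @return `params` with updated `c`, `d`.
#' @export
fit_readout_to_map <- function(params, P, n_steps = 500L, burn_in = 200L,
                               passes = 5L) {
  states <- mrnn_run(params, n_steps + 1L, burn_in = burn_in)
  for (it in seq_len(passes)) {
    y <- mrnn_readout(states, params)
    dom <- attr(P, "domain")
    y_in <- y[seq_len(n_steps)]
    if (!is.null(dom)) y_in <- pmin(pmax(y_in, dom[1]), dom[2])
    targets <- vapply(y_in, P, numeric(1))
    fit <- fit_readout(states[-1L, , drop = FALSE], targets)
    nc <- sqrt(sum(fit$c^2))
    if (nc == 0) break
    params$c <- fit$c / nc
    params$d <- fit$d / nc
  }
  params
}

#' Hebbian teacher forcing toward a 1D target map
#'
#' Trains the recurrent matrix with the dissipative outer-product rule
#' \deqn{\Delta W = \mu\left[(x^{tar}_{n+1} - (1-\gamma)x_n - b)\,
#'   \phi(x_n)^\top - \lambda W\right],}
#' where the target state shifts the achieved state along the readout
#' direction just enough to make its readout equal the target map value:
#' `x_tar_{n+1} = x_n + (P(y_n) - y_n) c`. Updates are averaged over a
#' short free-run batch per iteration. The spectral radius of `W` is
#' monitored and renormalized to 1 whenever it drifts outside
#' `[0.8, 1.2]`; each renormalization is logged. Training stops when the
#' mean one-step readout error falls below `tol`, when the update norm
#' falls below `tol`, or at `max_iter`.
#'
#' @param params an [mrnn_init()] object (readout should already be
#'   fitted, e.g. with [fit_readout_to_map()]).
#' @param P target 1D map.
#' @param mu_step learning rate.
#' @param lambda_reg weight decay.
#' @param tol stopping threshold on the time-averaged one-step error and
#'   on `||Delta W||_F`.
#' @param max_iter iteration cap.
#' @param n_steps batch length per iteration.
#' @param burn_in transient discarded per batch.
#' @return a list with the updated `params`, the per-iteration `trace` of
#'   the mean one-step error, `iterations`, and `renormalizations`.
#' @export
hebb_teacher_forcing <- function(params, P, mu_step = 0.005, lambda_reg = 1e-3,
                                 tol = 1e-3, max_iter = 100L, n_steps = 300L,
                                 burn_in = 100L) {
  err_of <- function(p) emulation_error(p, P, T_eval = n_steps,
                                        burn_in = burn_in)$E
  e0 <- err_of(params)
  if (!is.finite(e0)) pk_stop("non-finite error at entry", "peaknet_step_failure")
  trace <- e0
  if (e0 <= tol || mu_step == 0) {
    return(list(params = params, trace = trace, iterations = 0L,
                renormalizations = integer(0)))
  }
  renorms <- integer(0)
  for (it in seq_len(max_iter)) {
    states <- mrnn_run(params, n_steps + 1L, burn_in = burn_in)
    y <- mrnn_readout(states, params)
    dom <- attr(P, "domain")
    y_in <- if (is.null(dom)) y[seq_len(n_steps)] else
      pmin(pmax(y[seq_len(n_steps)], dom[1]), dom[2])
    Py <- vapply(y_in, P, numeric(1))
    dW <- matrix(0, params$m, params$m)
    for (n in seq_len(n_steps)) {
      x_n <- states[n, ]
      x_tar <- x_n + (Py[n] - y[n]) * params$c
      err_vec <- x_tar - (1 - params$gamma) * x_n - params$b
      dW <- dW + tcrossprod(err_vec, tanh(x_n))
    }
    dW <- mu_step * (dW / n_steps - lambda_reg * params$W)
    params$W <- params$W + dW
    rho <- spectral_radius(params$W)
    if (rho < 0.8 || rho > 1.2) {
      params$W <- params$W / rho
      renorms <- c(renorms, it)
    }
    e <- err_of(params)
    if (!is.finite(e)) pk_stop("error trace became non-finite", "peaknet_step_failure")
    trace <- c(trace, e)
    if (e <= tol || sqrt(sum(dW^2)) <= tol * mu_step) {
      return(list(params = params, trace = trace, iterations = it,
                  renormalizations = renorms))
    }
  }
  list(params = params, trace = trace, iterations = max_iter,
       renormalizations = renorms)
}
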