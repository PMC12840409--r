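#' Kropotov-Pakhomov network parameters
#'
#' Parameters of the binary-threshold recurrent network in its `original`
#' (raw synaptic sum, constant base weights) and `modified` (divisively
#' normalized drive, plastic base weights) variants. Neuron `i` updates its
#' potential
#' \deqn{P_i(k+1) = (1-\alpha) P_i(k) + \frac{\sum_j W_{ij}(k) N_j(k)}
#'   {\sum_j N_j(k) + 1} - \beta N_i(k) + S_i(k)}
#' (the divisive denominator is dropped in the original variant), with
#' effective weights `W_ij = (x_i1 + x_i2) W0_ij` scaled by the summed
#' synaptic efficacy, efficacy recurrences
#' `x_i1(k+1) = (1-A1) x_i1 + B1 N_i + C1` (and likewise `x_i2`), binary
#' activity `N_i = theta(P_i - h_i)` with `theta(x) = 0` for `x <= 0`, and
#' the delayed Bogdanov-Hebb base-weight rule
#' `W0(k+1) = (1-mu) W0(k) + upsilon * sum_m N_i(k) N_j(k-m)`.
#'
#' Default efficacy constants are `A1 = 0.4`, `A2 = B1 = C1 = 0.2`,
#' `B2 = 0.5`, `C2 = 0.1`, with `mu = 0.001` and `upsilon = 0.1`. The
#' potential dissipation `alpha` and post-spike drop `beta` are not pinned
#' by those defaults; `alpha = 0.1`, `beta = 0.5` keep unstimulated
#' potentials sub-threshold while allowing sustained recurrent activity.
#'
#' @param n number of neurons (default 64).
#' @param alpha potential dissipation in (0, 1).
#' @param beta post-spike potential drop (>= 0).
#' @param A1,A2 efficacy dissipation rates in \[0, 1\].
#' @param B1,B2,C1,C2 efficacy drive constants.
#' @param mu base-weight dissipation in \[0, 1\].
#' @param upsilon Hebb gain.
#' @param delays non-empty set of positive integer delays `{m}`.
#' @param thresholds activation thresholds `h_i >= 0` (scalar recycled).
#' @param variant `"modified"` or `"original"`.
#' @param hebb_rule `"delayed"` (decay + delayed coincidence), `"plain"`
#'   (no decay, fixed single delay), or `"none"`.
#' @return an object of class `kp_params`.
#' @export
kp_params <- function(n = 64L, alpha = 0.1, beta = 0.5,
                      A1 = 0.4, A2 = 0.2, B1 = 0.2, B2 = 0.5,
                      C1 = 0.2, C2 = 0.1, mu = 0.001, upsilon = 0.1,
                      delays = 1L, thresholds = 0,
                      variant = c("modified", "original"),
                      hebb_rule = c("delayed", "plain", "none")) {
  variant <- match.arg(variant)
  hebb_rule <- match.arg(hebb_rule)
  if (n < 1) pk_stop("n must be >= 1", "peaknet_invalid")
  for (nm in c("A1", "A2", "mu")) {
    v <- get(nm)
    if (v < 0 || v > 1) pk_stop(sprintf("%s must lie in [0, 1]", nm), "peaknet_invalid")
  }
  if (alpha <= 0 || alpha >= 1) pk_stop("alpha must lie in (0, 1)", "peaknet_invalid")
  if (any(thresholds < 0)) pk_stop("thresholds must satisfy h_i >= 0", "peaknet_invalid")
  if (length(delays) == 0L || any(delays < 1)) {
    pk_stop("delays must be positive integers", "peaknet_invalid")
  }
  structure(list(n = as.integer(n), alpha = alpha, beta = beta,
                 A1 = A1, A2 = A2, B1 = B1, B2 = B2, C1 = C1, C2 = C2,
                 mu = mu, upsilon = upsilon, delays = as.integer(delays),
                 thresholds = rep_len(thresholds, n), variant = variant,
                 hebb_rule = hebb_rule),
            class = "kp_params")
}

#' Initial network state
#'
#' All dynamic variables start at zero: potentials, activities, activators
#' and depressants, and both weight matrices; the activity history buffer
#' (deep enough for every delay) is zero-filled. Initialization is
#' deterministic given the seed, which is stored for the stimulation
#' protocol.
#'
#' @param params a [kp_params()] object.
#' @param seed integer seed recorded in the state.
#' @param W0_init optional initial base-weight matrix (used by the original
#'   variant, whose base weights stay constant).
#' @return an object of class `kp_state`.
#' @export
kp_init <- function(params, seed = 1L, W0_init = NULL) {
  n <- params$n
  depth <- max(params$delays) + 1L
  W0 <- if (is.null(W0_init)) matrix(0, n, n) else W0_init
  structure(list(k = 0L, P = numeric(n), N = integer(n),
                 x1 = numeric(n), x2 = numeric(n),
                 W0 = W0, W = (0) * W0,
                 history = matrix(0L, nrow = depth, ncol = n),
                 seed = as.integer(seed)),
            class = "kp_state")
}

#' @export
print.kp_state <- function(x, ...) {
  cat(sprintf("KP network state: %d neurons, k = %d, %d active\n",
              length(x$P), x$k, sum(x$N)))
  invisible(x)
}

#' Bogdanov-Hebb base-weight update
#'
#' `rule = "delayed"`: `W0(k+1) = (1 - mu) W0(k) +
#'   upsilon * sum_m N(k) N(k-m)^T` — multiplicative decay plus
#' temporally delayed coincidence, whose sustained-coincidence fixed point
#' is `upsilon / mu`. `rule = "plain"`: the undecayed accumulation
#' `W0 + upsilon * N(k) N(k-1)^T`, which grows without bound under
#' sustained co-activity (the synaptic-explosion ablation).
#' `rule = "none"` leaves `W0` untouched.
#'
#' @param W0 base-weight matrix.
#' @param N_history activity history, row 1 = `N(k)`, row `m+1` = `N(k-m)`.
#' @param mu decay parameter.
#' @param upsilon Hebb gain.
#' @param delays integer delay set `{m}`.
#' @param rule `"delayed"`, `"plain"`, or `"none"`.
#' @return the updated `W0`.
#' @export
hebb_update <- function(W0, N_history, mu, upsilon, delays = 1L,
                        rule = c("delayed", "plain", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(W0)
  if (max(delays) + 1L > nrow(N_history)) {
    pk_stop("delay exceeds history depth", "peaknet_invalid")
  }
  N_now <- N_history[1L, ]
  coinc <- matrix(0, nrow = length(N_now), ncol = length(N_now))
  for (m in delays) coinc <- coinc + tcrossprod(N_now, N_history[m + 1L, ])
  if (rule == "plain") W0 + upsilon * coinc
  else (1 - mu) * W0 + upsilon * coinc
}

#' Stimulation protocol
#'
#' During the first `duration` steps a pulse of size `amplitude` is applied
#' to `targets_per_step` uniformly drawn neurons at each step; afterwards
#' the stimulus is the zero vector.
#'
#' @param duration stimulation window in steps.
#' @param amplitude pulse magnitude.
#' @param targets_per_step neurons stimulated per step.
#' @return an object of class `kp_protocol`.
#' @export
kp_protocol <- function(duration = 2000L, amplitude = 0.5,
                        targets_per_step = 1L) {
  check_positive(amplitude, "amplitude")
  structure(list(duration = as.integer(duration), amplitude = amplitude,
                 targets_per_step = as.integer(targets_per_step)),
            class = "kp_protocol")
}

#' Stimulus vector at one time step
#'
#' Draws the target neurons with the current RNG stream (seed management
#' belongs to the caller; [kp_run()] seeds once per run).
#'
#' @param k time index (0-based).
#' @param protocol a [kp_protocol()].
#' @param n number of neurons.
#' @return a numeric stimulus vector.
#' @export
stimulate <- function(k, protocol, n) {
  S <- numeric(n)
  if (k < protocol$duration) {
    S[sample.int(n, protocol$targets_per_step)] <- protocol$amplitude
  }
  S
}

#' Advance the network by one step
#'
#' Applies the update order: potential (divisively normalized drive in the
#' modified variant, raw sum in the original), base weights (per the chosen
#' Hebb rule; constant in the original variant), efficacies, effective
#' weights, then the new binary activity, which is pushed onto the history
#' buffer. A potential exactly at threshold yields inactivity
#' (`theta(0) = 0`).
#'
#' @param state a `kp_state`.
#' @param S stimulus vector (scalar 0 allowed).
#' @param params a [kp_params()].
#' @return the state at `k + 1`.
#' @export
kp_step <- function(state, S, params) {
  n <- params$n
  S <- rep_len(S, n)
  N <- state$N
  drive <- as.numeric(state$W %*% N)
  if (params$variant == "modified") drive <- drive / (sum(N) + 1)
  P_new <- (1 - params$alpha) * state$P + drive - params$beta * N + S
  if (any(!is.finite(P_new))) {
    pk_stop("non-finite potential (divergence)", "peaknet_step_failure")
  }
  W0_new <- if (params$variant == "modified") {
    hebb_update(state$W0, state$history, params$mu, params$upsilon,
                params$delays, params$hebb_rule)
  } else {
    state$W0
  }
  x1_new <- (1 - params$A1) * state$x1 + params$B1 * N + params$C1
  x2_new <- (1 - params$A2) * state$x2 + params$B2 * N + params$C2
  W_new <- (x1_new + x2_new) * W0_new  # row scaling by postsynaptic efficacy
  N_new <- as.integer(P_new - params$thresholds > 0)
  history <- rbind(N_new, state$history[-nrow(state$history), , drop = FALSE])
  rownames(history) <- NULL
  structure(list(k = state$k + 1L, P = P_new, N = N_new,
                 x1 = x1_new, x2 = x2_new, W0 = W0_new, W = W_new,
                 history = history, seed = state$seed),
            class = "kp_state")
}

#' Run the network for many steps
#'
#' Seeds the RNG once from `seed`, then iterates [kp_step()] under the
#' stimulation protocol, recording the mean activity
#' `<N(k)> = sum_i N_i(k) / n`, the potential extrema, and (optionally) the
#' full activity raster and the ranges of the base weights and summed
#' efficacies used by the slow/fast scale-separation diagnostic.
#'
#' @param params a [kp_params()].
#' @param steps number of steps.
#' @param protocol a [kp_protocol()] (or `NULL` for no stimulation).
#' @param seed RNG seed for the stimulus draws.
#' @param record_activity keep the full binary raster (steps x n).
#' @param W0_init optional initial base weights (see [kp_init()]).
#' @param stimulus optional function `(k, n) -> stimulus vector`,
#'   overriding the protocol (used by ablation experiments).
#' @return a list of class `kp_run` with `mean_activity`, `P_min`, `P_max`,
#'   `G_max` (largest summed efficacy seen), `W0_max` (largest `|W0|`
#'   seen), per-step ranges `W0_range` and `G_range`, the final `state`,
#'   and `activity` when recorded.
#' @export
kp_run <- function(params, steps, protocol = kp_protocol(), seed = 1L,
                   record_activity = FALSE, W0_init = NULL, stimulus = NULL) {
  state <- kp_init(params, seed = seed, W0_init = W0_init)
  set.seed(seed)
  n <- params$n
  mean_activity <- numeric(steps)
  P_min <- numeric(steps); P_max <- numeric(steps)
  W0_range <- matrix(NA_real_, steps, 2); G_range <- matrix(NA_real_, steps, 2)
  activity <- if (record_activity) matrix(0L, steps, n) else NULL
  for (k in seq_len(steps)) {
    S <- if (!is.null(stimulus)) stimulus(state$k, n)
         else if (!is.null(protocol)) stimulate(state$k, protocol, n)
         else 0
    state <- kp_step(state, S, params)
    mean_activity[k] <- mean(state$N)
    P_min[k] <- min(state$P); P_max[k] <- max(state$P)
    W0_range[k, ] <- range(state$W0)
    g <- state$x1 + state$x2
    G_range[k, ] <- range(g)
    if (record_activity) activity[k, ] <- state$N
  }
  structure(list(mean_activity = mean_activity, P_min = P_min, P_max = P_max,
                 G_max = max(G_range[, 2]), W0_max = max(abs(W0_range)),
                 W0_range = W0_range, G_range = G_range,
                 state = state, activity = activity, params = params,
                 steps = steps, seed = seed),
            class = "kp_run")
}

#' @export
print.kp_run <- function(x, ...) {
  cat(sprintf("KP run: %d neurons, %d steps, final mean activity %.3f\n",
              x$params$n, x$steps, utils::tail(x$mean_activity, 1)))
  invisible(x)
}

#' Limiting summed synaptic efficacy
#'
#' Closed-form fixed point of the efficacy recurrences at constant activity
#' `N`: \deqn{x_1 + x_2 \to \frac{B_1 N + C_1}{A_1} + \frac{B_2 N + C_2}{A_2},}
#' together with the value actually reached by iterating the recurrences
#' from zero (agreement is a consistency check; at the default constants
#' and `N = 0` the limit is exactly 1).
#'
#' @param params a [kp_params()].
#' @param N_const constant activity, 0 or 1.
#' @param iterations iteration count for the numeric check.
#' @return a list with `value` (closed form) and `iterated`.
#' @export
efficacy_fixed_point <- function(params = kp_params(), N_const = 0,
                                 iterations = 1e4) {
  if (params$A1 == 0 || params$A2 == 0) {
    pk_stop("no fixed point when A1 or A2 is zero", "peaknet_degenerate")
  }
  value <- (params$B1 * N_const + params$C1) / params$A1 +
           (params$B2 * N_const + params$C2) / params$A2
  x1 <- 0; x2 <- 0
  for (k in seq_len(iterations)) {
    x1 <- (1 - params$A1) * x1 + params$B1 * N_const + params$C1
    x2 <- (1 - params$A2) * x2 + params$B2 * N_const + params$C2
  }
  list(value = value, iterated = x1 + x2)
}
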