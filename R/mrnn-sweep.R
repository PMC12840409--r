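#' Bifurcation sweep of the recurrent operator
#'
#' Varies `eta` (at fixed `gamma`) or `gamma` (at fixed `eta`) over a grid;
#' for each value the operator free-runs from a seeded initial state, the
#' transient is discarded, and the local maxima of the observed variable
#' (first state coordinate by default) are recorded. The per-value count of
#' distinct peak heights reads off the fixed-point / period-2 / chaotic
#' bands of the diagram. Documented grids are `eta` in `[0.2, 1.6]` at
#' `gamma = 0.25` and `gamma` in `[0.0, 0.9]`; values outside them warn.
#' Divergence at a grid point is logged and the sweep continues.
#'
#' @param params an [mrnn_init()] object (its `eta`/`gamma` provide the
#'   fixed complementary parameter).
#' @param vary `"eta"` or `"gamma"`.
#' @param grid strictly increasing numeric grid.
#' @param burn_in transient steps discarded (default 2000).
#' @param n_peaks peaks recorded per grid value (default 200).
#' @param observable state coordinate index observed, or `"readout"`.
#' @param run_steps free-run length scanned for peaks after burn-in.
#' @param distinct_tol absolute tolerance used to count distinct peaks
#'   (default `1e-4` of the per-value peak range).
#' @return a list of class `mrnn_sweep` with `diagram` (long data.frame
#'   `param, peak`), `summary` (data.frame `param, n_peaks_found,
#'   n_distinct`), `vary`, and `failures`.
#' @export
mrnn_sweep <- function(params, vary = c("eta", "gamma"), grid,
                       burn_in = 2000L, n_peaks = 200L, observable = 1L,
                       run_steps = 4000L, distinct_tol = NULL) {
  vary <- match.arg(vary)
  if (length(grid) == 0L) pk_stop("empty grid", "peaknet_invalid")
  if (is.unsorted(grid, strictly = TRUE)) {
    pk_stop("grid must be strictly increasing", "peaknet_invalid")
  }
  doc_range <- if (vary == "eta") c(0.2, 1.6) else c(0.0, 0.9)
  if (min(grid) < doc_range[1] - 1e-12 || max(grid) > doc_range[2] + 1e-12) {
    warning(sprintf("grid extends outside the documented %s range [%g, %g]",
                    vary, doc_range[1], doc_range[2]))
  }
  rows <- vector("list", length(grid))
  summ <- vector("list", length(grid))
  failures <- list()
  for (i in seq_along(grid)) {
    p <- params
    p[[vary]] <- grid[i]
    res <- tryCatch({
      states <- mrnn_run(p, run_steps, burn_in = burn_in)
      series <- if (identical(observable, "readout")) mrnn_readout(states, p)
                else states[, observable]
      pk <- detect_peaks(series, refine = FALSE)
      heights <- utils::tail(pk$heights, n_peaks)
      if (length(heights) == 0L) {
        # no interior maxima: the orbit settled on a fixed point; record it
        heights <- utils::tail(series, 1L)
      }
      heights
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(grid[i])]] <- conditionMessage(res)
      next
    }
    tol_i <- if (is.null(distinct_tol)) {
      rng <- diff(range(res))
      1e-4 * max(rng, 1e-8)
    } else distinct_tol
    rows[[i]] <- data.frame(param = grid[i], peak = res)
    summ[[i]] <- data.frame(param = grid[i], n_peaks_found = length(res),
                            n_distinct = count_distinct(res, tol_i))
  }
  structure(list(diagram = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                 summary = do.call(rbind, summ[!vapply(summ, is.null, logical(1))]),
                 vary = vary, failures = failures),
            class = "mrnn_sweep")
}

#' @export
print.mrnn_sweep <- function(x, ...) {
  cat(sprintf("MRNN %s-sweep over %d grid points (%d failures)\n",
              x$vary, nrow(x$summary), length(x$failures)))
  invisible(x)
}

#' Grid search over network parameters with stability pruning
#'
#' Coarse-to-fine scan of the Kropotov-Pakhomov parameter space minimizing
#' the objective
#' \deqn{J = \alpha\,\sigma_x + \beta\,\sigma_e + \gamma\,D_W,}
#' where `sigma_x` is the variance of the membrane potentials over time
#' (stability), `sigma_e` the variance of the summed efficacies
#' (convergence), and `D_W` the normalized deviation of the base weights
#' (structural constancy). Candidates are pruned before scoring:
#' divergence or guard escape rejects with reason `"unbounded"`; an
#' empirical one-step amplification rate of a small state perturbation
#' above `lambda_max` rejects with reason `"spectral"` (the binary network
#' has no smooth Jacobian, so the growth rate of a perturbed twin run
#' stands in for its top multiplier); an output variance below `var_min`
#' rejects with reason `"degenerate"`. A second pass refines a halved-
#' spacing grid around the coarse minimizer.
#'
#' @param ranges named list of candidate values per parameter (any subset
#'   of the [kp_params()] arguments, e.g. `list(A1 = c(.2,.4,.6))`).
#' @param weights length-3 balancing coefficients `(alpha, beta, gamma)`
#'   of `J`.
#' @param K_steps simulation length per candidate.
#' @param thresholds list with `lambda_max` (default 1.05) and `var_min`.
#' @param base a [kp_params()] supplying the non-scanned parameters.
#' @param protocol stimulation protocol for the candidate runs.
#' @param seed RNG seed.
#' @param refine do the fine pass.
#' @param objective optional replacement objective
#'   `function(theta) -> J` (bypasses simulation scoring; pruning is
#'   skipped), used for validation against known surfaces.
#' @return a list of class `grid_search_result` with `theta` (the accepted
#'   minimizer as a [kp_params()]), `J`, `evaluations` (data.frame), and
#'   `rejections` (data.frame with reasons).
#' @export
grid_search <- function(ranges, weights = c(1, 1, 1), K_steps = 2000L,
                        thresholds = list(lambda_max = 1.05, var_min = 1e-10),
                        base = kp_params(n = 16L), protocol = kp_protocol(duration = 500L),
                        seed = 1L, refine = TRUE, objective = NULL) {
  if (length(ranges) == 0L || is.null(names(ranges))) {
    pk_stop("ranges must be a named list", "peaknet_invalid")
  }
  evaluate_grid <- function(grids) {
    cand <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    evals <- list(); rejects <- list()
    for (r in seq_len(nrow(cand))) {
      theta <- as.list(cand[r, , drop = FALSE])
      if (!is.null(objective)) {
        evals[[length(evals) + 1L]] <- cbind(cand[r, , drop = FALSE],
                                             J = objective(theta))
        next
      }
      p <- tryCatch(do.call(kp_params, utils::modifyList(unclass(base), theta)),
        error = function(e) e)
      if (inherits(p, "error")) {
        rejects[[length(rejects) + 1L]] <- cbind(cand[r, , drop = FALSE],
                                                 reason = "invalid")
        next
      }
      score <- tryCatch(kp_candidate_score(p, K_steps, protocol, seed, thresholds),
                        error = function(e) list(reject = "unbounded"))
      if (!is.null(score$reject)) {
        rejects[[length(rejects) + 1L]] <- cbind(cand[r, , drop = FALSE],
                                                 reason = score$reject)
        next
      }
      J <- sum(weights * c(score$sigma_x, score$sigma_e, score$D_W))
      evals[[length(evals) + 1L]] <- cbind(cand[r, , drop = FALSE], J = J)
    }
    list(evals = if (length(evals)) do.call(rbind, evals) else NULL,
         rejects = if (length(rejects)) do.call(rbind, rejects) else NULL)
  }
  coarse <- evaluate_grid(ranges)
  if (is.null(coarse$evals)) {
    cond <- errorCondition("all candidates rejected",
                           class = c("peaknet_degenerate", "peaknet_error"))
    cond$rejections <- coarse$rejects
    stop(cond)
  }
  best <- coarse$evals[which.min(coarse$evals$J), , drop = FALSE]
  evals <- coarse$evals; rejects <- coarse$rejects
  if (refine) {
    fine_ranges <- lapply(names(ranges), function(nm) {
      vals <- sort(unique(ranges[[nm]]))
      if (length(vals) < 2L) return(vals)
      step <- min(diff(vals)) / 2
      ctr <- best[[nm]]
      sort(unique(pmax(min(vals), pmin(max(vals), ctr + step * (-1:1)))))
    })
    names(fine_ranges) <- names(ranges)
    fine <- evaluate_grid(fine_ranges)
    if (!is.null(fine$evals)) {
      evals <- rbind(evals, fine$evals)
      best <- evals[which.min(evals$J), , drop = FALSE]
    }
    rejects <- rbind(rejects, fine$rejects)
  }
  theta <- do.call(kp_params, utils::modifyList(
    unclass(base), as.list(best[setdiff(names(best), "J")])))
  structure(list(theta = theta, J = best$J, evaluations = evals,
                 rejections = rejects),
            class = "grid_search_result")
}

# score one KP parameter candidate; NULL-reject fields on pruning
kp_candidate_score <- function(p, K_steps, protocol, seed, thresholds) {
  run <- tryCatch(kp_run(p, K_steps, protocol = protocol, seed = seed),
                  error = function(e) e)
  if (inherits(run, "error")) return(list(reject = "unbounded"))
  if (max(abs(c(run$P_min, run$P_max))) > 1e4) return(list(reject = "unbounded"))
  # empirical top-multiplier proxy: growth of a twin run with one extra pulse
  amp <- kp_perturbation_rate(p, K_steps, protocol, seed)
  if (is.finite(amp) && amp > thresholds$lambda_max) {
    return(list(reject = "spectral"))
  }
  act_var <- stats::var(run$mean_activity)
  if (act_var < thresholds$var_min) return(list(reject = "degenerate"))
  g_mid <- (run$G_range[, 1] + run$G_range[, 2]) / 2
  w_dev <- run$W0_range[, 2] - run$W0_range[, 1]
  list(sigma_x = stats::var((run$P_min + run$P_max) / 2),
       sigma_e = stats::var(g_mid),
       D_W = mean(w_dev) / max(run$W0_max, .Machine$double.eps))
}

# geometric mean per-step amplification of a small initial perturbation
kp_perturbation_rate <- function(p, K_steps, protocol, seed, delta = 1e-3,
                                 horizon = 200L) {
  horizon <- min(horizon, K_steps)
  run_pair <- function(extra) {
    state <- kp_init(p, seed = seed)
    set.seed(seed)
    state$P[1] <- state$P[1] + extra
    traceP <- matrix(NA_real_, horizon, p$n)
    for (k in seq_len(horizon)) {
      S <- if (!is.null(protocol)) stimulate(state$k, protocol, p$n) else 0
      state <- kp_step(state, S, p)
      traceP[k, ] <- state$P
    }
    traceP
  }
  base_tr <- run_pair(0)
  pert_tr <- run_pair(delta)
  gap <- sqrt(rowSums((base_tr - pert_tr)^2))
  gap <- gap[gap > 0]
  if (length(gap) < 2L) return(0)
  exp(mean(diff(log(gap))))
}

#' Network-size selection for 1D-map emulation
#'
#' For each candidate dimension `m` the operator is built with spectral
#' radius 1, the readout is fitted to the target map, and the candidate is
#' scored by `E(m) + lambda C(m)` with `E(m)` the mean one-step emulation
#' error and `C(m) = m^2 / max(M)^2` a parameter-count-proportional
#' complexity penalty. Candidates must also pass two matching gates:
#' `|lambda_MRNN - lambda_P| < eps_lyap` (top Lyapunov exponents of the
#' operator and of the target map) and a Hausdorff distance below
#' `delta_hausdorff` between the observed peak set of the readout and the
#' target map's orbit closure. The minimal total score among gate-passing
#' candidates wins; if no candidate passes, the best-effort ranking is
#' still returned with `m_star = NA`.
#'
#' @param candidates integer candidate dimensions, e.g.
#'   `c(8, 16, 32, 64, 100, 128)`.
#' @param P target 1D map.
#' @param lambda_penalty complexity weight.
#' @param eps_lyap Lyapunov-gap gate.
#' @param delta_hausdorff Hausdorff-distance gate.
#' @param eta,gamma operator control parameters used for all candidates.
#' @param seed RNG seed.
#' @param n_eval evaluation steps for `E(m)` and the diagnostics.
#' @param diagnostics optional function
#'   `function(m) -> list(E, lyap_gap, hausdorff)` replacing the simulated
#'   diagnostics (validation hook for planted-score checks).
#' @return a list of class `size_selection_result` with `m_star`, `table`
#'   (per-candidate scores and gate flags), and `passed`.
#' @export
select_size <- function(candidates, P, lambda_penalty = 0.05,
                        eps_lyap = 1, delta_hausdorff = 0.5,
                        eta = 0.9, gamma = 0.25, seed = 1L, n_eval = 400L,
                        diagnostics = NULL) {
  if (length(candidates) == 0L) pk_stop("empty candidate set", "peaknet_invalid")
  lam_P <- NULL
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    m <- candidates[i]
    if (!is.null(diagnostics)) {
      d <- diagnostics(m)
    } else {
      if (is.null(lam_P)) {
        lam_P <- lyapunov_map(P, map_deriv(P), 0.3, n = 5000L,
                              burn_in = 100L)$exponents[1]
      }
      pars <- mrnn_init(m, eta = eta, gamma = gamma, seed = seed)
      pars <- fit_readout_to_map(pars, P, n_steps = n_eval, burn_in = 200L)
      E <- emulation_error(pars, P, T_eval = n_eval, burn_in = 200L)$E
      lam_m <- tryCatch(
        lyapunov_map(function(x) mrnn_step(x, pars),
                     function(x) mrnn_jacobian(x, pars),
                     x0 = rep(0.1, m), n = 500L, burn_in = 200L)$exponents[1],
        error = function(e) NA_real_)
      y <- mrnn_readout(mrnn_run(pars, n_eval, burn_in = 2000L), pars)
      pk <- detect_peaks(y, refine = FALSE)$heights
      orbit <- iterate_map(P, 0.3, 10000L, burn_in = 100L)
      d <- list(E = E, lyap_gap = abs(lam_m - lam_P),
                hausdorff = hausdorff_dist(pk, orbit))
    }
    C <- (m / max(candidates))^2
    rows[[i]] <- data.frame(m = m, E = d$E, C = C,
                            score = d$E + lambda_penalty * C,
                            lyap_gap = d$lyap_gap, hausdorff = d$hausdorff,
                            passes = is.finite(d$lyap_gap) &&
                              d$lyap_gap < eps_lyap &&
                              d$hausdorff < delta_hausdorff)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$score), ]
  ok <- tab[tab$passes, , drop = FALSE]
  m_star <- if (nrow(ok)) ok$m[1] else NA_integer_
  structure(list(m_star = m_star, table = tab, passed = nrow(ok) > 0),
            class = "size_selection_result")
}
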