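test_that("initialization normalizes the spectral radius and is reproducible", {
  p <- mrnn_init(seed = 4)
  expect_equal(p$m, 64L)
  expect_close(spectral_radius(p$W), 1, 1e-6)
  expect_close(sqrt(sum(p$c^2)), 1, 1e-12)
  expect_identical(mrnn_init(16, seed = 9), mrnn_init(16, seed = 9))
  expect_error(mrnn_init(16, gamma = 1.5), class = "peaknet_invalid")
})

test_that("the step map honours its fixed point, decay limit, and saturation bound", {
  p <- mrnn_init(12, eta = 0.8, gamma = 0.3, seed = 2)
  expect_equal(mrnn_step(numeric(12), p), numeric(12))
  p0 <- p; p0$eta <- 1e-300  # eta must stay positive; the drive is negligible
  x <- stats::rnorm(12)
  expect_close(mrnn_step(x, p0), (1 - p0$gamma) * x, 1e-12)
  # saturation: the nonlinear drive is bounded by eta ||W|| sqrt(m)
  xl <- rep(1e6, 12)
  drive <- mrnn_step(xl, p) - (1 - p$gamma) * xl
  expect_lte(sqrt(sum(drive^2)),
             p$eta * norm(p$W, "2") * sqrt(12) + 1e-9)
})

test_that("the jacobian matches finite differences and its saturation limits", {
  p <- mrnn_init(8, eta = 0.9, gamma = 0.25, seed = 3)
  expect_equal(mrnn_jacobian(numeric(8), p),
               (1 - p$gamma) * diag(8) + p$eta * p$W)
  set.seed(5)
  for (rep in 1:3) {
    x <- stats::rnorm(8)
    J <- mrnn_jacobian(x, p)
    Jfd <- matrix(0, 8, 8)
    for (j in 1:8) {
      e <- numeric(8); e[j] <- 1e-6
      Jfd[, j] <- (mrnn_step(x + e, p) - mrnn_step(x - e, p)) / 2e-6
    }
    expect_close(J, Jfd, 1e-6)
  }
  expect_close(mrnn_jacobian(rep(50, 8), p), (1 - p$gamma) * diag(8), 1e-12)
})

test_that("monodromy products, spectra, and the gelfand cross-check agree", {
  # T = 1 reduces to the jacobian at the fixed point
  p <- mrnn_init(8, eta = 0.1, gamma = 0.25, seed = 3)
  m1 <- monodromy(matrix(0, 1, 8), params = p, tol = 1e-10)
  expect_equal(m1$M, mrnn_jacobian(numeric(8), p))
  # diagonal linear system with rates (a, b): rho(M_T) = max(|a|,|b|)^T
  set.seed(2)
  orbit <- matrix(stats::rnorm(6), 3, 2)
  mr <- monodromy(orbit, jacobian = function(x) diag(c(0.7, -0.5)))
  expect_close(mr$spectral_radius, 0.7^3, 1e-12)
  expect_close(gelfand_radius(mr$M, 50), mr$spectral_radius,
               0.01 * mr$spectral_radius)
  # an unclosed orbit is rejected with the gap reported
  err <- tryCatch(monodromy(matrix(c(5, 5, 5, 5, 5, 5, 5, 5), 1, 8),
                            params = p, tol = 1e-10),
                  error = identity)
  expect_s3_class(err, "peaknet_invalid")
  expect_true(err$gap > 0)
})

test_that("monodromy of an embedded cycle equals the 1D multiplier, and its label predicts perturbation decay", {
  oracle <- logistic_two_cycle(3.2)
  emb <- embed_block_map(logistic_map(3.2), c(0.3, -0.2))
  orbit <- rbind(c(oracle$points[1], 0, 0), c(oracle$points[2], 0, 0))
  mr <- monodromy(orbit, jacobian = emb$jacobian, map = emb$map, tol = 1e-8)
  expect_close(mr$spectral_radius, abs(oracle$multiplier), 1e-8)
  expect_equal(mr$label, "stable")
  # direct perturbation of the stable cycle contracts over a few periods
  x <- orbit[1, ] + c(1e-4, 1e-4, 1e-4)
  for (k in 1:10) x <- emb$map(x)
  expect_lt(max(abs(x - orbit[1, ])), 1e-4 / 2)
})

test_that("readout fitting is an exact least-squares solve with rank handling", {
  set.seed(6)
  states <- matrix(stats::rnorm(200 * 5), 200, 5)
  c0 <- stats::rnorm(5); d0 <- 0.7
  fit <- fit_readout(states, as.numeric(states %*% c0) + d0)
  expect_close(fit$c, c0, 1e-8)
  expect_close(fit$d, d0, 1e-8)
  expect_lt(fit$residual, 1e-10)
  expect_false(fit$rank_deficient)
  # optimality: no random perturbation of the solution does better
  y <- as.numeric(states %*% c0) + d0 + stats::rnorm(200, sd = 0.1)
  fit <- fit_readout(states, y)
  obj <- function(cc, dd) sum((states %*% cc + dd - y)^2)
  best <- obj(fit$c, fit$d)
  for (i in 1:100) {
    expect_lte(best, obj(fit$c + stats::rnorm(5, sd = 0.01),
                         fit$d + stats::rnorm(1, sd = 0.01)))
  }
  # identical states: rank-deficiency is flagged, minimum-norm returned
  same <- matrix(1, 50, 5)
  expect_true(fit_readout(same, rep(2, 50))$rank_deficient)
  # nested least squares: on the common data the restricted fit is optimal,
  # so the full-data coefficients cannot beat it there
  fit_half <- fit_readout(states[1:100, ], y[1:100])
  ssr_half_of <- function(cc, dd) sum((states[1:100, ] %*% cc + dd - y[1:100])^2)
  expect_lte(ssr_half_of(fit_half$c, fit_half$d),
             ssr_half_of(fit$c, fit$d) + 1e-10)
})

test_that("emulation error vanishes for a perfect emulator and matches constants", {
  # gamma = 1, eta ~ 0, b = 0: the state pins to 0, the readout is d, and
  # an identity target map gives zero one-step error
  p <- mrnn_init(4, eta = 1e-300, gamma = 1, seed = 1)
  p$d <- 0.4
  ident <- structure(function(z) z, class = c("map1d", "function"))
  expect_equal(emulation_error(p, ident, T_eval = 50)$E, 0)
  # constant readout y against a known map: E = |P(y) - y| analytically
  P <- logistic_map(3.2)
  e <- emulation_error(p, P, T_eval = 50)$E
  expect_close(e, abs(P(0.4) - 0.4), 1e-12)
  expect_error(emulation_error(p, P, T_eval = 0), class = "peaknet_invalid")
})

test_that("teacher forcing stops immediately when met and reduces the error monotonically", {
  P <- logistic_map(3.2)
  p <- mrnn_init(64, eta = 0.9, gamma = 0.25, seed = 1)
  p <- fit_readout_to_map(p, P)
  # mu = 0: parameters unchanged exactly
  out <- hebb_teacher_forcing(p, P, mu_step = 0, lambda_reg = 0, tol = 1e-12,
                              max_iter = 5)
  expect_identical(out$params$W, p$W)
  expect_equal(out$iterations, 0L)
  # already-met target returns after 0 iterations
  e0 <- emulation_error(p, P, T_eval = 300, burn_in = 100)$E
  out <- hebb_teacher_forcing(p, P, tol = e0 * 2, max_iter = 5)
  expect_equal(out$iterations, 0L)
  # degraded recurrent weights: the monitored error decreases strictly
  set.seed(7)
  pd <- p
  pd$W <- pd$W + matrix(stats::rnorm(64 * 64, sd = 0.02), 64, 64)
  out <- hebb_teacher_forcing(pd, P, mu_step = 0.005, tol = 1e-3,
                              max_iter = 100)
  first <- out$trace[seq_len(min(11, length(out$trace)))]
  expect_true(all(diff(first) < 0))
  expect_lt(utils::tail(out$trace, 1), out$trace[1])
})

test_that("the operator contracts to a unique fixed point below the gain threshold", {
  # (1 - gamma) + eta rho(W) < 1 forces global contraction toward one point
  p <- mrnn_init(16, eta = 0.2, gamma = 0.9, seed = 2)
  set.seed(11)
  ends <- replicate(100, {
    x <- stats::rnorm(16, sd = 2)
    for (i in 1:300) x <- mrnn_step(x, p)
    x
  })
  expect_lt(max(apply(ends, 1, function(r) diff(range(r)))), 1e-10)
})

test_that("eta sweeps resolve the fixed-point band and single-point grids", {
  p <- mrnn_init(16, eta = 0.9, gamma = 0.25, seed = 1)
  sw <- mrnn_sweep(p, "eta", 0.5, burn_in = 200L, run_steps = 400L)
  expect_equal(nrow(sw$summary), 1L)
  # eta ~ 0.2 with gamma = 0.25: spectral radius below 1, a single point
  sw0 <- mrnn_sweep(p, "eta", c(0.2, 0.22), burn_in = 1000L, run_steps = 500L)
  expect_true(all(sw0$summary$n_distinct <= 1))
  expect_error(mrnn_sweep(p, "eta", numeric(0)), class = "peaknet_invalid")
  expect_warning(mrnn_sweep(p, "eta", c(1.9, 2.0), burn_in = 50L,
                            run_steps = 100L))
})

test_that("grid search recovers a planted objective and prunes honestly", {
  # known convex surface on the grid: exhaustive evaluation finds its minimum
  gs <- grid_search(list(A1 = c(0.2, 0.4, 0.6), mu = c(0.001, 0.01)),
                    objective = function(th) (th$A1 - 0.4)^2 + (th$mu - 0.01)^2,
                    refine = FALSE)
  expect_equal(gs$theta$A1, 0.4)
  expect_equal(gs$theta$mu, 0.01)
  # a single passing candidate is returned as theta*
  gs1 <- grid_search(list(A1 = 0.4), K_steps = 400L, refine = FALSE,
                     base = kp_params(n = 8L),
                     protocol = kp_protocol(duration = 200L))
  expect_equal(gs1$theta$A1, 0.4)
  # an over-threshold variance floor rejects every candidate as degenerate
  err <- tryCatch(
    grid_search(list(A1 = 0.4), K_steps = 400L, refine = FALSE,
                base = kp_params(n = 8L), protocol = kp_protocol(duration = 200L),
                thresholds = list(lambda_max = 1.05, var_min = 1e6)),
    error = identity)
  expect_s3_class(err, "peaknet_degenerate")
  expect_true(all(err$rejections$reason == "degenerate"))
})

test_that("size selection scores planted optima and degrades gracefully", {
  P <- logistic_map(3.2)
  planted <- select_size(c(8, 16, 32, 64, 100, 128), P, lambda_penalty = 0.05,
                         diagnostics = function(m)
                           list(E = (m - 64)^2 / 1e4, lyap_gap = 0.1,
                                hausdorff = 0.1))
  expect_equal(planted$m_star, 64)
  # identical errors: the complexity penalty picks the smallest network
  flat <- select_size(c(8, 16, 32), P,
                      diagnostics = function(m)
                        list(E = 0.5, lyap_gap = 0.1, hausdorff = 0.1))
  expect_equal(flat$m_star, 8)
  expect_error(select_size(integer(0), P), class = "peaknet_invalid")
  # simulated path returns a complete ranking even when the gates fail
  real <- select_size(c(8, 16), P, n_eval = 150L, seed = 1)
  expect_equal(sort(real$table$m), c(8, 16))
  expect_true(all(is.finite(real$table$score)))
})

test_that("the embedding harness reproduces the three reference verdicts", {
  P <- structure(function(z) z, class = c("map1d", "function"))
  lin <- function(slope) {
    f <- function(z) slope * z
    attr(f, "deriv") <- function(z) slope
    class(f) <- c("map1d", "function")
    f
  }
  r1 <- conjugate_embedding_test(lin(0.5), 0, rep(0.8, 3))
  expect_equal(r1$rho, 0.8)
  expect_true(r1$stable_P && r1$stable_F && r1$equivalent)
  expect_false(r1$assumption_violated)
  r2 <- conjugate_embedding_test(lin(1.5), 0, rep(0.5, 3))
  expect_equal(r2$rho, 1.5)
  expect_true(!r2$stable_P && !r2$stable_F && r2$equivalent)
  r3 <- conjugate_embedding_test(lin(0.5), 0, c(1.3))
  expect_equal(r3$rho, 1.3)
  expect_false(r3$equivalent)
  expect_true(r3$assumption_violated)
  expect_error(conjugate_embedding_test(lin(0.5), 0, c(1)), class = "peaknet_invalid")
})
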