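test_that("initial state is all-zero and deterministic; defaults match the model", {
  p <- kp_params()
  expect_equal(p$n, 64L)
  expect_equal(c(p$A1, p$A2, p$B1, p$B2, p$C1, p$C2), c(0.4, 0.2, 0.2, 0.5, 0.2, 0.1))
  expect_equal(c(p$mu, p$upsilon), c(0.001, 0.1))
  st <- kp_init(p, seed = 7)
  expect_true(all(st$P == 0) && all(st$N == 0) && all(st$x1 == 0) &&
                all(st$x2 == 0) && all(st$W0 == 0) && all(st$W == 0) &&
                all(st$history == 0))
  expect_identical(kp_init(p, seed = 7), kp_init(p, seed = 7))
  expect_error(kp_params(A1 = 1.5), class = "peaknet_invalid")
  expect_error(kp_params(thresholds = -1), class = "peaknet_invalid")
})

test_that("one step from rest populates only the efficacy constants", {
  p <- kp_params()
  st <- kp_step(kp_init(p), 0, p)
  expect_equal(st$x1, rep(0.2, 64))
  expect_equal(st$x2, rep(0.1, 64))
  expect_true(all(st$P == 0) && all(st$N == 0))
})

test_that("threshold and normalization details follow the update rules", {
  p <- kp_params(n = 3L, alpha = 0.5, beta = 0)
  st <- kp_init(p)
  # potential exactly at threshold stays inactive: theta(0) = 0
  st1 <- kp_step(st, c(0, 0, 0), p)
  expect_equal(st1$N, c(0L, 0L, 0L))
  st2 <- kp_step(st, c(0.4, 0, 0), p)
  expect_equal(st2$N, c(1L, 0L, 0L))
  # one active presynaptic neuron: divisive denominator is sum(N) + 1 = 2
  st2$W <- matrix(1, 3, 3)
  st3 <- kp_step(st2, 0, p)
  drive <- (st2$W %*% st2$N) / (sum(st2$N) + 1)
  expect_equal(st3$P, as.numeric((1 - p$alpha) * st2$P + drive))
})

test_that("hebb updates decay, accumulate, converge, and superpose", {
  # all-inactive history: pure decay
  H <- matrix(0L, 2, 2)
  W0 <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(hebb_update(W0, H, 0.01, 0.1, 1L, "delayed"), 0.99 * W0)
  expect_identical(hebb_update(W0, H, 0.01, 0.1, 1L, "none"), W0)
  # sustained coincidence: the delayed rule approaches upsilon / mu = 100
  H1 <- matrix(1L, 2, 1)
  w <- matrix(0, 1, 1)
  for (k in 1:10000) w <- hebb_update(w, H1, 0.001, 0.1, 1L, "delayed")
  expect_equal(w[1, 1], 100 * (1 - 0.999^10000), tolerance = 1e-10)
  expect_close(w[1, 1], 100, 0.01)
  # plain rule with no decay accumulates upsilon per step
  w <- matrix(0, 1, 1)
  for (k in 1:10) w <- hebb_update(w, H1, 0.001, 0.1, 1L, "plain")
  expect_equal(w[1, 1], 1.0)
  # linearity in W0 of the delayed rule: superposition holds exactly
  set.seed(12)
  A <- matrix(stats::rnorm(4), 2); B <- matrix(stats::rnorm(4), 2)
  H2 <- matrix(rbinom(4, 1, 0.5), 2, 2)
  lhs <- hebb_update(A + 2 * B, H2, 0.01, 0.1, 1L, "delayed")
  rhs <- hebb_update(A, H2, 0.01, 0.1, 1L, "delayed") +
    2 * hebb_update(B, H2, 0.01, 0.1, 1L, "delayed") -
    2 * hebb_update(0 * B, H2, 0.01, 0.1, 1L, "delayed")
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(hebb_update(W0, H, 0.01, 0.1, 5L, "delayed"),
               class = "peaknet_invalid")
})

test_that("the stimulation protocol hits one neuron inside the window and none after", {
  prot <- kp_protocol(duration = 10L, amplitude = 0.5)
  set.seed(3)
  S <- stimulate(0, prot, 64)
  expect_equal(sum(S != 0), 1L)
  expect_equal(S[S != 0], 0.5)
  expect_equal(stimulate(10, prot, 64), numeric(64))
  set.seed(99); a <- replicate(5, which(stimulate(1, prot, 64) != 0))
  set.seed(99); b <- replicate(5, which(stimulate(1, prot, 64) != 0))
  expect_identical(a, b)
})

test_that("efficacy fixed points match the closed form over random parameter draws", {
  p <- kp_params()
  fp0 <- efficacy_fixed_point(p, 0)
  expect_equal(fp0$value, 1)
  expect_close(fp0$iterated, 1, 1e-10)
  fp1 <- efficacy_fixed_point(p, 1)
  expect_equal(fp1$value, 4)
  expect_close(fp1$iterated, 4, 1e-10)
  # full replacement converges in one step
  p1 <- kp_params(A1 = 1, A2 = 1)
  expect_equal(efficacy_fixed_point(p1, 1, iterations = 1)$iterated,
               p1$B1 + p1$C1 + p1$B2 + p1$C2)
  expect_error(efficacy_fixed_point(kp_params(A1 = 0)), class = "peaknet_degenerate")
  set.seed(17)
  for (i in 1:100) {
    pr <- kp_params(A1 = stats::runif(1, 0.05, 1), A2 = stats::runif(1, 0.05, 1),
                    B1 = stats::runif(1), B2 = stats::runif(1),
                    C1 = stats::runif(1), C2 = stats::runif(1))
    fp <- efficacy_fixed_point(pr, sample(0:1, 1))
    expect_close(fp$iterated, fp$value, 1e-10)
  }
})

test_that("periodic closed forms reduce correctly in the limiting cases", {
  # constant forcing: geometric series b / (1 - a)
  expect_close(periodic_closed_form(0.3, rep(2, 4)), 2 / 0.7, 1e-12)
  # a = 0: only the last term survives, A(k) = b(k + T - 1)
  b <- c(5, 7, 11)
  expect_equal(periodic_closed_form(0, b), b[c(3, 1, 2)])
  expect_error(periodic_closed_form(1, b), class = "peaknet_degenerate")
})

test_that("stationary link weights follow the periodic closed form", {
  # permanently co-active pair: upsilon / mu, matching the hebb limit
  expect_close(link_weights_periodic(c(1L, 1L), c(1L, 1L), 0.001, 0.1),
               100, 1e-8)
  expect_equal(link_weights_periodic(c(1L, 0L), c(1L, 0L), 0.01, 0.1),
               c(0, 0))
  expect_error(link_weights_periodic(c(1L, 1L), c(1L, 1L), 0, 0.1),
               class = "peaknet_degenerate")
})

test_that("link-type counting identifies phase-shifted product sequences", {
  expect_equal(count_link_types(matrix(0L, 20, 2), 1), 1L)
  anti <- generate_fixture("binary_blocks",
                           list(block = matrix(c(1L, 0L, 0L, 1L), 2, 2)),
                           length = 20, seed = 1)
  expect_equal(count_link_types(anti, 2), 2L)
  expect_equal(count_link_types(matrix(1L, 20, 2), 1), 1L)
  expect_error(count_link_types(matrix(rbinom(40, 1, 0.5), 20, 2), 3),
               class = "peaknet_degenerate")
})

test_that("regime reports detect zeroing, exact tiling, and aperiodicity", {
  set.seed(5)
  z <- rbind(matrix(rbinom(50 * 6, 1, 0.5), 50, 6), matrix(0L, 30, 6))
  rz <- kp_regime_report(z)
  expect_true(rz$zeroed)
  expect_equal(rz$label, "zeroed")
  expect_lte(rz$T_life, 51L)
  blk <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 1), 4, 4,
                byrow = TRUE)
  r4 <- kp_regime_report(generate_fixture("binary_blocks", list(block = blk),
                                          length = 200, seed = 1))
  expect_equal(r4$label, "periodic")
  expect_equal(r4$period, 4L)
  expect_true(r4$amplitude_ok && r4$period_ok && r4$autocorr_ok)
  set.seed(5)
  rnd <- matrix(rbinom(300 * 16, 1, 0.5), 300, 16)
  expect_equal(kp_regime_report(rnd, T_max = 12)$label, "non_periodic_stable")
  expect_error(kp_regime_report(rnd, interval = c(100, 1000)),
               class = "peaknet_invalid")
})

test_that("block-frequency profiles decompose binary activity with unit mass", {
  fp <- frequency_profile(matrix(rep(c(0L, 1L), 50), ncol = 1))
  expect_equal(fp$lengths, 1L)
  expect_equal(fp$g, 1)
  expect_equal(fp$frequency, 0.5)
  fp2 <- frequency_profile(matrix(rep(c(0L, 0L, 1L, 1L), 25), ncol = 1))
  expect_equal(fp2$lengths, 2L)
  expect_equal(fp2$g, 1)
  set.seed(8)
  fpr <- frequency_profile(matrix(rbinom(600, 1, 0.4), 200, 3))
  expect_close(sum(fpr$g), 1, 1e-12)
})

test_that("slow weights drift far below the fast efficacies under flickering activity", {
  # time-scale separation at the default constants: drive both recurrences
  # with the same alternating activity and compare normalized per-step rates
  p <- kp_params()
  K <- 4000
  N1 <- rep(c(1L, 0L), K / 2); N2 <- rep(c(0L, 1L), K / 2)
  x1 <- 0; x2 <- 0; w <- 0
  w_tr <- numeric(K); g_tr <- numeric(K)
  for (k in 2:K) {
    w <- (1 - p$mu) * w + p$upsilon * N1[k] * N2[k - 1]
    x1 <- (1 - p$A1) * x1 + p$B1 * N1[k] + p$C1
    x2 <- (1 - p$A2) * x2 + p$B2 * N1[k] + p$C2
    w_tr[k] <- w; g_tr[k] <- x1 + x2
  }
  rate <- function(x) mean(abs(diff(x))) / diff(range(x))
  int <- 2000:K
  expect_lte(rate(w_tr[int]) / rate(g_tr[int]), 0.1)
})
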