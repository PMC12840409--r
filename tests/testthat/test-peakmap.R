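test_that("peak detection refines parabolas exactly and resolves sine extrema", {
  # quadratic interpolation is exact for parabolic data
  t <- seq(0, 2, by = 0.1)
  pk <- detect_peaks(-(t - 1)^2, t = t, refine = TRUE)
  expect_equal(length(pk$heights), 1L)
  expect_close(pk$times, 1, 1e-12)
  expect_close(pk$heights, 0, 1e-12)
  # strictly monotone series has no peaks
  expect_equal(length(detect_peaks(seq(0, 1, by = 0.01))$heights), 0L)
  # sine peaks are 2 pi apart after refinement
  t <- seq(0, 20, by = 0.01)
  pk <- detect_peaks(sin(t), t = t, refine = TRUE)
  expect_close(diff(pk$times), 2 * pi, 1e-3)
  expect_close(pk$heights, 1, 1e-6)
  # plateaus longer than two samples are flagged degenerate
  s <- c(0, 1, 2, 2, 2, 1, 0)
  pk <- detect_peaks(s, refine = TRUE)
  expect_true(any(pk$degenerate))
  expect_error(detect_peaks(c(1, 2)), class = "peaknet_insufficient_data")
})

test_that("peak pairs reproduce the generating map", {
  expect_equal(nrow(build_peak_pairs(1:5)), 4L)
  cp <- build_peak_pairs(rep(0.5, 6))
  expect_true(all(cp$z == cp$z_next))
  z <- iterate_map(logistic_map(3.7), 0.2, 200)
  pr <- build_peak_pairs(z)
  expect_close(pr$z_next, 3.7 * pr$z * (1 - pr$z), 1e-12)
  expect_error(build_peak_pairs(1), class = "peaknet_insufficient_data")
})

test_that("local slope recovers map derivatives from orbit data", {
  # linear map: slope is exact for any window
  z <- iterate_map(function(x) 0.6 * x + 0.2, 0.9, 50)
  expect_equal(local_slope(build_peak_pairs(z), 0.5, 10), 0.6, tolerance = 1e-10)
  # logistic r = 2.8 near its fixed point: slope tends to 2 - r = -0.8
  P <- logistic_map(2.8)
  z <- iterate_map(P, 0.21, 80)
  pr <- build_peak_pairs(z)
  z_star <- logistic_fixed_point(2.8)
  wide <- local_slope(pr, z_star, 0.1)
  narrow <- local_slope(pr, z_star, 0.02)
  expect_close(wide, -0.8, 0.05)
  expect_close(narrow, -0.8, 0.02)
  expect_error(local_slope(build_peak_pairs(c(1, 2, 3)), 2, 1e-9),
               class = "peaknet_insufficient_data")
})

test_that("cycle search matches logistic closed forms and keeps minimal periods", {
  cyc <- find_cycles(logistic_map(3.2), c(0, 1), T_max = 2, tol = 1e-12)
  periods <- vapply(cyc, `[[`, integer(1), "period")
  two <- cyc[[which(periods == 2L)]]
  oracle <- logistic_two_cycle(3.2)
  expect_close(sort(two$points), oracle$points, 1e-8)
  expect_close(two$multiplier, oracle$multiplier, 1e-8)
  expect_equal(two$stability, "stable")
  # r = 2.8: the interior fixed point exists, but no genuine 2-cycle
  cyc <- find_cycles(logistic_map(2.8), c(0, 1), T_max = 2, tol = 1e-12)
  periods <- vapply(cyc, `[[`, integer(1), "period")
  expect_false(any(periods == 2L))
  fps <- vapply(cyc[periods == 1L], function(cc) cc$points[1], numeric(1))
  expect_true(any(abs(fps - logistic_fixed_point(2.8)) < 1e-8))
  # identity map raises the degenerate-map flag
  ident <- structure(function(z) z, class = c("map1d", "function"))
  expect_true(attr(find_cycles(ident, c(0, 1), 1), "degenerate"))
})

test_that("cycle multipliers are rotation-invariant products of derivatives", {
  expect_equal(cycle_multiplier(0.4, function(z) 0.7), 0.7)
  oracle <- logistic_two_cycle(3.2)
  d <- attr(logistic_map(3.2), "deriv")
  m1 <- cycle_multiplier(oracle$points, d)
  m2 <- cycle_multiplier(rev(oracle$points), d)
  expect_lt(abs(m1 - m2) / abs(m1), 1e-12)
  expect_close(m1, 0.16, 1e-12)
  expect_error(cycle_multiplier(0.5, function(z) Inf), class = "peaknet_nonfinite")
})

test_that("stability classification splits at the unit circle with a marginal band", {
  expect_equal(classify_stability(0.16), "stable")
  expect_equal(classify_stability(-1.2), "unstable")
  expect_equal(classify_stability(1.0), "marginal")
  expect_equal(classify_stability(-1 + 1e-9), "marginal")
})

test_that("recurrence profile counts returns exactly", {
  z3 <- rep(c(0.1, 0.5, 0.9), 30)
  rp <- recurrence_profile(z3, 4, epsilon = 1e-6)
  expect_equal(unname(rp$r[3]), 1)
  expect_lt(rp$r[1], 1); expect_lt(rp$r[2], 1)
  expect_true(all(recurrence_profile(rep(0.5, 40), 5)$r == 1))
  # iid uniform heights: P(|U - U'| < eps) = 2 eps - eps^2
  set.seed(31)
  rp <- recurrence_profile(stats::runif(4000), 5, epsilon = 0.05)
  expect_close(rp$r, 2 * 0.05 - 0.05^2, 0.02)
  expect_error(recurrence_profile(1:5, 10), class = "peaknet_insufficient_data")
})

test_that("regime classification separates periodic, chaotic and constant orbits", {
  # attracting 2-cycle, observed with its transient so the slope fit works
  z <- iterate_map(logistic_map(3.2), 0.2, 300, burn_in = 3)
  lab <- classify_regime(z)
  expect_equal(lab$label, "periodic_stable")
  expect_equal(lab$evidence$T, 2L)
  expect_lt(abs(lab$evidence$Lambda), 1)
  expect_close(lab$evidence$Lambda, 0.16, 0.05)
  # fully chaotic logistic orbit: no observable periodicity
  z4 <- iterate_map(logistic_map(4), 0.2, 500, burn_in = 100)
  expect_equal(classify_regime(z4, theta = 0.8)$label, "non_periodic_unstable")
  # constant heights are a 1-cycle
  lab1 <- classify_regime(rep(0.5, 50))
  expect_equal(lab1$label, "periodic_stable")
  expect_equal(lab1$evidence$T, 1L)
})

test_that("empirical contraction rates match the multiplier (linear stability)", {
  # stable fixed point of r = 2.8: iterate convergence ratio ~ |Lambda_1| = 0.8
  P <- logistic_map(2.8)
  z_star <- logistic_fixed_point(2.8)
  z <- z_star + 1e-3
  d <- numeric(8)
  for (i in 1:8) { d[i] <- z - z_star; z <- P(z) }
  expect_close(abs(d[-1] / d[-8]), 0.8, 0.8 * 0.05)
})

test_that("refined peak heights converge at the integrator's rate", {
  peak_err <- function(scheme, h) {
    tr <- integrate_system(c(1, 0), harmonic_f, h, round(7 / h), scheme = scheme)
    abs(detect_peaks(tr, coord = 1)$heights[1] - 1)
  }
  hs <- c(0.08, 0.04, 0.02, 0.01)
  expect_close(loglog_slope(hs, vapply(hs, function(h) peak_err("euler", h),
                                       numeric(1))), 1, 0.3)
  expect_gte(loglog_slope(hs, vapply(hs, function(h) peak_err("rk4", h),
                                     numeric(1))), 2)
})
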