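# shared fixtures and oracle helpers, built in code at test time

classical <- lorenz_params()
lorenz_f <- function(s) lorenz_field(s, classical)
lorenz_J <- function(s) lorenz_jacobian(s, classical)

# a point on the attractor, reached deterministically from (1,1,1)
on_attractor <- integrate_system(c(1, 1, 1), lorenz_f, 0.01, 3000)$states[3001, ]

# log-log slope of err(h)
loglog_slope <- function(hs, errs) {
  unname(stats::coef(stats::lm(log(errs) ~ log(hs)))[2])
}

# self-convergence global error at T = 1 time unit against an h/4 reference
self_convergence_error <- function(scheme, h, x0 = on_attractor) {
  a <- integrate_system(x0, lorenz_f, h, round(1 / h), scheme = scheme)
  b <- integrate_system(x0, lorenz_f, h / 4, round(4 / h), scheme = scheme)
  max(abs(a$states[nrow(a$states), ] - b$states[nrow(b$states), ]))
}

# planar harmonic oscillator: exact peaks of the first coordinate at height 1
harmonic_f <- function(s) c(s[2], -s[1])

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 8), collapse = ","), tol,
                              paste(signif(expected, 8), collapse = ",")))
}
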