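test_that("plain model has the documented extrema and integral", {
  expect_equal(model_eq1(0.7, 0.2, 1.5, 0.7), 1.7)
  expect_equal(model_eq1(0.7 + pi / 2, 0.2, 1.5, 0.7), 0.2,
               tolerance = 1e-12)
  # integral over one period: pi * (y0 + A/2), by numeric quadrature
  q <- integrate(model_eq1, 0, pi, y0 = 0.3, A = 2, x = 1.1,
                 rel.tol = 1e-10)$value
  expect_equal(q, pi * (0.3 + 1), tolerance = 1e-8)
})

test_that("narrowed model nests the plain one and keeps its peak", {
  set.seed(2)
  a <- runif(1e4, 0, pi); y0 <- runif(1e4, 0, 2)
  A <- runif(1e4, 0, 3); x <- runif(1e4, 0, pi)
  expect_equal(model_eq2(a, y0, A, x, 0), model_eq1(a, y0, A, x),
               tolerance = 1e-15)
  for (f in c(0.5, 2, 10))
    expect_equal(model_eq2(0.9, 1, 2, 0.9, f), 3)
  expect_error(model_eq2(1, 0, 1, 0, -1), "f")
})

test_that("eq2 FWHM matches a numeric root-finding oracle", {
  for (f in c(0, 0.3, 2, 5, 20)) {
    if (f == 0) {
      expect_equal(eq2_fwhm(0), pi / 2) # 90 degrees
    } else {
      half <- function(D) cos(D)^2 / (1 + f * sin(D)^2) - 0.5
      D_half <- uniroot(half, c(1e-9, pi / 2 - 1e-9), tol = 1e-12)$root
      expect_equal(eq2_fwhm(f), 2 * D_half, tolerance = 1e-6)
    }
  }
  expect_equal(eq2_fwhm(2), pi / 3, tolerance = 1e-12) # 60 degrees
})

test_that("fitting recovers noiseless narrowed-model parameters", {
  a <- angles_n(50)
  tr <- model_eq2(a, 0.2, 1, pi / 3, 5)
  fit <- fit_modulation(tr, a)
  expect_lt(abs(fit$y0 - 0.2), 1e-6)
  expect_lt(abs(fit$A - 1) / 1, 1e-6)
  expect_lt(axis_dist(fit$x, pi / 3), 1e-6)
  expect_lt(abs(fit$f - 5) / 5, 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
})

test_that("degenerate traces are handled without blowing up", {
  expect_error(fit_modulation(rep(1, 4)), "at least")
  flat <- fit_modulation(rep(2, 12))
  expect_equal(flat$A, 0)
  expect_equal(flat$r2, 0)
  # a plain trace fitted with the narrowed model gives f ~ 0
  a <- angles_n(30)
  fit <- fit_modulation(model_eq1(a, 0.5, 2, 0.7), a)
  expect_lt(fit$f, 1e-3)
})

test_that("eq2 never fits worse than eq1 (model nesting)", {
  set.seed(7)
  a <- angles_n(15)
  for (i in 1:20) {
    tr <- model_eq1(a, runif(1, 0, 1), runif(1, 0.5, 2), runif(1, 0, pi)) +
      rnorm(15, 0, 0.05)
    f1 <- fit_modulation(tr, a, model = "eq1")
    f2 <- fit_modulation(tr, a, model = "eq2")
    sse <- function(f) sum((tr[order(frexpan:::mod_pi(a))] - f$fitted)^2)
    # nesting holds analytically; allow the finite optimizer tolerance
    expect_lte(sse(f2), sse(f1) * (1 + 1e-3) + 1e-8)
  }
})

test_that("the fitted phase is identifiable modulo pi", {
  a <- angles_n(24)
  set.seed(5)
  for (i in 1:10) {
    x_true <- runif(1, 0, pi)
    tr <- model_eq2(a, 0.1, 1, x_true, 3) + rnorm(24, 0, 0.02)
    fit <- fit_modulation(tr, a)
    expect_lt(axis_dist(fit$x, x_true), 0.1)
    expect_true(fit$x >= 0 && fit$x < pi)
  }
})
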