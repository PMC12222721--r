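test_that("the three-parameter model has the documented shape", {
  tg <- 2 * pi * (0:11) / 12
  p <- list(I0 = matrix(0, 1, 1), A = matrix(1, 1, 1), B = matrix(0, 1, 1))
  m <- alpa_forward(p, gaussian_psf(1e-3), tg)
  tr <- m[, 1, 1]
  expect_equal(max(tr), 2) # at t = 0
  expect_equal(min(tr), 0, tolerance = 1e-12) # at t = pi
  # property: the trace never goes below I0 for random quadratures
  set.seed(8)
  for (i in 1:20) {
    p <- list(I0 = matrix(runif(1), 1, 1), A = matrix(rnorm(1), 1, 1),
              B = matrix(rnorm(1), 1, 1))
    tr <- alpa_forward(p, gaussian_psf(1e-3), seq(0, 2 * pi, length.out = 64))
    expect_gte(min(tr), p$I0[1, 1] - 1e-12)
  }
})

test_that("initialisation from the DFT is exact on pure model traces", {
  N <- 12
  tg <- 2 * pi * (0:(N - 1)) / N
  set.seed(4)
  I0 <- matrix(runif(9, 0, 0.5), 3); A <- matrix(rnorm(9), 3)
  B <- matrix(rnorm(9), 3)
  R <- sqrt(A^2 + B^2)
  d <- array(0, c(N, 3, 3))
  for (k in seq_len(N)) d[k, , ] <- I0 + A * cos(tg[k]) - B * sin(tg[k]) + R
  init <- alpa_init(image_stack(d, N))
  expect_equal(init$A, A, tolerance = 1e-9)
  expect_equal(init$B, B, tolerance = 1e-9)
  expect_equal(init$I0, I0, tolerance = 1e-9)
  # constant trace: A = B = 0, I0 = mean
  cinit <- alpa_init(image_stack(array(3, c(8, 2, 2)), 8))
  expect_equal(cinit$A, matrix(0, 2, 2))
  expect_equal(cinit$I0, matrix(3, 2, 2))
  # negative provisional offsets are clamped to zero
  d2 <- array(0, c(N, 1, 1))
  for (k in seq_len(N)) d2[k, , ] <- cos(tg[k]) # mean 0 < amplitude
  expect_equal(alpa_init(image_stack(d2, N))$I0[1, 1], 0)
})

test_that("ALPA with a delta PSF reproduces FFT demodulation phases", {
  set.seed(6)
  N <- 12; nr <- 12
  a <- angles_n(N)
  y0 <- matrix(runif(nr^2, 0, 0.2), nr)
  A1 <- matrix(runif(nr^2, 0.5, 2), nr)
  x <- matrix(runif(nr^2, 0, pi), nr)
  stk <- model_stack(N, y0, A1, x, angles = a)
  al <- alpa_deconvolve(stk, gaussian_psf(1e-3), n_iter = 400)
  pm <- fft_demodulate(stk)
  expect_lt(max(axis_dist(al$phase, pm$phase)), 1e-6)
  expect_lt(max(abs(al$amplitude - pm$amplitude / 2)), 1e-6)
  expect_lt(al$objective, 1e-12)
})

test_that("the objective is non-increasing as iterations accumulate", {
  fx <- sim_crossing(n_angles = 8, shape = 24L)
  objs <- vapply(c(5, 20, 60), function(n)
    alpa_deconvolve(fx$period, gaussian_psf(2), n_iter = n)$objective,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-8 * objs[1]))
})

test_that("blurred two-emitter phases are recovered to < 2 degrees", {
  N <- 12
  a <- angles_n(N)
  det <- ideal_detector(shape = c(24, 24), psf_sigma = 2 * 45, seed = 1)
  xy <- rbind(c(8, 12), c(16, 12)) * 45
  ph_true <- c(0.4, 1.9)
  d <- array(0, c(N, 24, 24))
  for (k in seq_len(N))
    d[k, , ] <- render_frame(xy, 800 * cos(a[k] - ph_true)^2, det,
                             noise = FALSE)
  al <- alpa_deconvolve(image_stack(d, N, angles = a), gaussian_psf(2),
                        n_iter = 800)
  for (i in 1:2) {
    px <- round(xy[i, ] / 45 + 0.5)
    expect_lt(axis_dist(al$phase[px[2], px[1]], ph_true[i]),
              2 * pi / 180)
  }
})
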