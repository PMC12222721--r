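test_that("mean normalization fixes every pixel's temporal mean to 1", {
  d <- array(0, c(4, 2, 2))
  d[, 1, 1] <- c(5, 5, 5, 5)
  d[, 2, 1] <- c(2, 4, 2, 4)
  d[, 1, 2] <- c(1, 2, 3, 4)
  # pixel (2,2) stays all-zero
  stk <- mean_normalize(image_stack(d, 4))
  expect_equal(stk$data[, 1, 1], rep(1, 4))
  expect_equal(stk$data[1:2, 2, 1], c(2 / 3, 4 / 3))
  expect_equal(stk$data[, 2, 2], rep(0, 4))
  expect_true(attr(stk, "zero_mask")[2, 2])
  # property: random stacks
  set.seed(1)
  r <- image_stack(array(rexp(5 * 3 * 3) + 0.1, c(5, 3, 3)), 5)
  mn <- mean_normalize(r)
  expect_equal(apply(mn$data, c(2, 3), mean), matrix(1, 3, 3))
  expect_warning(mean_normalize(image_stack(array(0, c(3, 2, 2)), 3)),
                 "all-zero")
})

test_that("demultiplexing reproduces the frame accounting of the pulse scheme", {
  s <- sim_vesicle_frexpan(n_frames = 34, n_lead = 4, shape = c(16L, 16L),
                           density = 20)
  ro <- demux_frexpan(s$sim$stack, 4)
  expect_equal(n_frames(ro), 15)
  expect_equal(ro$frames_per_period, 15)
  expect_true(all(ro$roles == "readout"))
  # without labels the alternation convention applies; odd remainders fail
  unl <- s$sim$stack; unl$roles <- NULL
  expect_equal(n_frames(demux_frexpan(unl, 4)), 15)
  expect_error(demux_frexpan(unl, 5), "29 frames")
  # all-readout stack with n_cut = 0 is the identity
  fpm <- image_stack(array(1:24, c(6, 2, 2)), 6,
                     roles = rep("readout", 6))
  expect_equal(demux_frexpan(fpm, 0)$data, fpm$data)
})

test_that("periodic averaging compresses whole periods and drops the tail", {
  base <- array(rnorm(5 * 2 * 2), c(5, 2, 2))
  three <- image_stack(abs(base[c(1:5, 1:5, 1:5), , , drop = FALSE]) + 1, 5)
  avg <- periodic_average(three)
  expect_equal(avg$data, abs(base) + 1, tolerance = 1e-12)
  # N = n_frames: identity
  one <- image_stack(abs(base) + 1, 5)
  expect_equal(periodic_average(one)$data, one$data)
  # trailing partial period is dropped
  tail17 <- image_stack(abs(array(rnorm(17 * 2 * 2), c(17, 2, 2))) + 1, 5)
  expect_equal(dim(periodic_average(tail17)$data)[1], 5)
  expect_equal(periodic_average(tail17)$data,
               periodic_average(image_stack(tail17$data[1:15, , ], 5))$data)
  expect_error(periodic_average(image_stack(base, 7)), "fewer than one period")
})

test_that("FFT demodulation is exact on noiseless model traces", {
  # worked N = 4 example: y0 = 1, A = 2, x = 0
  pm4 <- fft_demodulate(image_stack(array(c(3, 2, 1, 2), c(4, 1, 1)), 4))
  expect_equal(pm4$amplitude[1, 1], 2)
  expect_equal(pm4$phase[1, 1], 0)
  expect_equal(pm4$offset[1, 1], 2)
  set.seed(3)
  for (N in c(15, 30, 50)) {
    y0 <- matrix(runif(4, 0, 1), 2)
    A1 <- matrix(runif(4, 0.5, 2), 2)
    x <- matrix(runif(4, 0, pi), 2)
    pm <- fft_demodulate(model_stack(N, y0, A1, x))
    expect_lt(max(abs(pm$amplitude - A1)), 1e-9)
    expect_lt(max(axis_dist(pm$phase, x)), 1e-9)
    expect_lt(max(abs(pm$offset - (y0 + A1 / 2))), 1e-9)
  }
  # constant trace: zero amplitude, masked phase 0
  pmc <- fft_demodulate(image_stack(array(2, c(8, 1, 1)), 8))
  expect_equal(pmc$amplitude[1, 1], 0)
  expect_equal(pmc$phase[1, 1], 0)
  expect_true(pmc$mask[1, 1])
  expect_error(fft_demodulate(image_stack(array(1, c(3, 1, 1)), 3)),
               "at least 4")
})

test_that("demodulation accounts for the first frame's polarization angle", {
  N <- 15
  a <- angles_n(N) + 0.4 # acquisition started mid-rotation
  pm <- fft_demodulate(model_stack(N, matrix(0.1, 1, 1),
                                   matrix(1.5, 1, 1), matrix(1.2, 1, 1),
                                   angles = a))
  expect_lt(axis_dist(pm$phase[1, 1], 1.2), 1e-9)
})

test_that("the processing chain recovers simulated phases to < 0.5 degree", {
  # two well-separated straight membranes: every pixel of a filament sees
  # a single dipole orientation, so the chain's phase must be exact
  g <- make_geometry("two_membranes", length = 2200, gap = 1100,
                     angle = 0.9, center = c(1440, 1440))
  f <- populate_dipoles(g, 120, "double", seed = 8, c_dt = 1, D_lat = 0)
  plan <- acquisition_plan(90, 30, "fpm")
  det <- ideal_detector(shape = c(64, 64), seed = 1)
  sim <- simulate_stack(f, plan, det, store_truth = FALSE)
  pm <- fft_demodulate(periodic_average(mean_normalize(sim$stack)))
  tru <- true_orientation_map(g, det)
  m <- mean_image(sim$stack)
  sel <- tru$mask & m > quantile(m, 0.97)
  expect_gt(sum(sel), 20)
  err <- axis_dist(pm$phase[sel], (0.9 + pi / 2) %% pi)
  expect_lt(median(err), 0.5 * pi / 180)
})

test_that("periodic averaging reduces Poisson noise like the period count", {
  set.seed(21)
  N <- 6; reps <- 200; lam <- 50
  v1 <- numeric(reps); v6 <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- array(rpois(N * 6 * 4 * 4, lam), c(N * 6, 4, 4))
    stk <- image_stack(d, N)
    avg <- periodic_average(stk)
    v1[r] <- var(as.numeric(d))
    v6[r] <- var(as.numeric(avg$data))
  }
  expect_lt(abs(mean(v1) / mean(v6) - 6) / 6, 0.2)
})

test_that("phase rendering maps amplitude and phase as documented", {
  pm <- list(offset = matrix(1, 4, 4), amplitude = matrix(0, 4, 4),
             phase = matrix(0, 4, 4), mask = matrix(TRUE, 4, 4),
             pixel_size = 45)
  class(pm) <- "phase_map"
  expect_true(all(phase_color_render(pm) == 0)) # zero amplitude: black
  # two-colour coding separates regions across the threshold
  pm$amplitude <- matrix(1, 4, 4)
  pm$phase <- matrix(c(rep(0.2, 8), rep(1.4, 8)), 4, 4)
  rgb <- phase_color_render(pm, "two_color", threshold = 0.8)
  expect_true(all(rgb[, 1:2, 1] == 1) && all(rgb[, 1:2, 2] == 0))
  expect_true(all(rgb[, 3:4, 2] == 1) && all(rgb[, 3:4, 1] == 0))
  # hue is pi-periodic
  pm2 <- pm; pm2$phase <- pm$phase + pi
  expect_equal(phase_color_render(pm), phase_color_render(pm2))
})
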