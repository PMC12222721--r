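test_that("FrExPAN frame roles and angles follow the pulse scheme", {
  plan <- acquisition_plan(700, 100, "frexpan", 100)
  roles <- frame_roles(plan)
  expect_equal(sum(roles == "lead"), 100)
  expect_equal(sum(roles == "switch"), 300)
  expect_equal(sum(roles == "readout"), 300)
  # readout frames are exactly every second frame after the leads
  expect_equal(which(roles == "readout"), seq(102, 700, by = 2))
  # polarization advances pi / frames_per_period per frame
  expect_equal(angle_of_frame(plan, 1), 0)
  expect_equal(angle_of_frame(plan, 2), pi / 100)
  expect_equal(angle_of_frame(plan, 101), 0) # one period later
  expect_error(acquisition_plan(701, 100, "frexpan", 100), "even")
  expect_error(acquisition_plan(700, 15, "frexpan", 100), "even")
})

test_that("plain FPM of a rigid dipole peaks at the aligned frame", {
  g <- make_geometry("segment", length = 500, center = c(1400, 1400))
  f <- populate_dipoles(g, 2, "double", seed = 1, anchor_offset = 0.9,
                        c_dt = 1, D_lat = 0)
  f$s <- 250; f$contour <- 1L; f$on <- TRUE
  plan <- acquisition_plan(30, 30, "fpm")
  det <- ideal_detector(shape = c(64, 64), seed = 1)
  sim <- simulate_stack(f, plan, det)
  totals <- apply(sim$stack$data, 1, sum)
  k_best <- which.max(totals)
  expect_lt(axis_dist(angle_of_frame(plan, k_best), 0.9), pi / 30 + 1e-9)
})

test_that("simulation is bit-reproducible from the same seeds", {
  s1 <- sim_vesicle_frexpan(det_seed = 5, n_frames = 34, n_lead = 4,
                            shape = c(32L, 32L), density = 40)
  s2 <- sim_vesicle_frexpan(det_seed = 5, n_frames = 34, n_lead = 4,
                            shape = c(32L, 32L), density = 40)
  expect_identical(s1$sim$stack$data, s2$sim$stack$data)
  s3 <- sim_vesicle_frexpan(det_seed = 6, n_frames = 34, n_lead = 4,
                            shape = c(32L, 32L), density = 40)
  expect_false(identical(s1$sim$stack$data, s3$sim$stack$data))
})

test_that("noiseless bright-pixel traces follow the plain modulation model", {
  ctr <- c(1440, 1440)
  g <- make_geometry("circle", r = 450, center = ctr)
  f <- populate_dipoles(g, 100, "double", seed = 4, D_lat = 0)
  plan <- acquisition_plan(30, 30, "fpm")
  det <- ideal_detector(shape = c(64, 64), seed = 1)
  sim <- simulate_stack(f, plan, det)
  m <- mean_image(sim$stack)
  bright <- which(m >= sort(m, decreasing = TRUE)[5], arr.ind = TRUE)
  for (i in seq_len(nrow(bright))) {
    tr <- sim$stack$data[, bright[i, 1], bright[i, 2]]
    fit <- fit_modulation(tr, sim$stack$angles, model = "eq1")
    expect_gt(fit$r2, 0.999)
  }
})

test_that("modulation amplitude scales with the order parameter", {
  # identical scene and seed, double vs single tag: the FFT amplitude maps
  # differ by c_dt / c_st on membrane pixels
  ctr <- c(2160, 2160)
  g <- make_geometry("circle", r = 900, center = ctr)
  det <- ideal_detector(shape = c(96, 96), seed = 5)
  plan <- acquisition_plan(30, 30, "fpm")
  pms <- lapply(c("double", "single"), function(tm) {
    fld <- populate_dipoles(g, 100, tm, seed = 7, D_lat = 0)
    fft_demodulate(periodic_average(simulate_stack(fld, plan, det,
                                                   store_truth = FALSE)$stack))
  })
  sel <- pms[[1]]$amplitude > 0.2 * max(pms[[1]]$amplitude)
  ratio <- median(pms[[1]]$amplitude[sel] / pms[[2]]$amplitude[sel])
  expect_lt(abs(ratio - 0.95 / 0.2) / (0.95 / 0.2), 0.05)
})

test_that("ground truth records what is needed to audit a frame", {
  s <- sim_vesicle_frexpan(n_frames = 22, n_lead = 2, shape = c(32L, 32L),
                           density = 40, store_truth = TRUE)
  tr <- s$sim$truth
  expect_equal(dim(tr$orientations), c(22, tr$n_dipoles))
  expect_equal(dim(tr$expected_photons), c(22, tr$n_dipoles))
  expect_true(all(is.finite(tr$orientations)))
  expect_equal(tr$seed, s$det$seed)
})
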