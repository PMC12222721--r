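# Shared fixtures: everything is generated in code, no stored data.

# circular distance between two axis angles (radians, modulo pi)
axis_dist <- function(a, b) abs(((a - b) + pi / 2) %% pi - pi / 2)

# evenly spaced polarization angles over one period
angles_n <- function(N) pi * (seq_len(N) - 1) / N

# a noiseless FrExPAN readout trace of a single oriented population
frexpan_trace <- function(alpha, b, phi = 0.9, cc = 0.95, a_on = 6) {
  c2 <- cos(alpha - phi)^2
  (1 - exp(-a_on * c2)) * exp(-b * (1 - c2)) * ((1 - cc) / 2 + c2 * cc)
}

# single-vesicle FrExPAN acquisition used by several tests
sim_vesicle_frexpan <- function(det_seed = 2, field_seed = 101,
                                dose_off = 3, switch_brightness = 3,
                                n_frames = 190, n_lead = 10,
                                shape = c(64L, 64L), density = 100,
                                store_truth = FALSE) {
  ctr <- shape * 45 / 2
  g <- make_geometry("circle", r = 450, center = ctr)
  fld <- populate_dipoles(g, density, "double", seed = field_seed)
  plan <- acquisition_plan(n_frames, 30, "frexpan", n_lead,
                           dose_off = dose_off,
                           switch_brightness = switch_brightness)
  det <- detector_model(shape = shape, seed = det_seed)
  sim <- simulate_stack(fld, plan, det, render_method = "splat",
                        store_truth = store_truth)
  list(sim = sim, geom = g, plan = plan, det = det, n_lead = n_lead)
}

# demux + normalize + periodic average
prep_period <- function(stack, n_cut) {
  periodic_average(mean_normalize(demux_frexpan(stack, n_cut)))
}

# crossing-filament plain-FPM scene for the deconvolution tests
sim_crossing <- function(n_angles = 12L, psf_sigma_px = 2, shape = 64L,
                         seed = 9) {
  ext <- shape * 45
  g <- make_geometry("crossing_filaments", angles = c(0, pi / 3),
                     length = 2200, center = c(ext / 2, ext / 2))
  fld <- populate_dipoles(g, 120, "double", seed = seed, c_dt = 1, D_lat = 0)
  plan <- acquisition_plan(n_angles, n_angles, "fpm")
  det <- ideal_detector(shape = c(shape, shape), psf_sigma = psf_sigma_px * 45,
                        seed = 1)
  sim <- simulate_stack(fld, plan, det, store_truth = FALSE)
  list(period = periodic_average(sim$stack), geom = g, det = det)
}

# synthetic stack whose pixel traces follow the plain modulation model
model_stack <- function(N, y0, A1, x, angles = NULL) {
  angles <- angles %||% angles_n(N)
  d <- array(0, c(N, dim(y0)[1], dim(y0)[2]))
  for (k in seq_len(N)) d[k, , ] <- y0 + A1 * cos(angles[k] - x)^2
  image_stack(d, N, angles = angles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
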