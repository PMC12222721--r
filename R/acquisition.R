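#' Polarization-rotation acquisition plan
#'
#' Describes how camera frames map to excitation polarization angles and
#' pulse roles.  The polarization advances by `pi / frames_per_period_acq`
#' per camera frame (one modulation period is \eqn{\pi} of rotation, since
#' the cos-squared response is \eqn{\pi}-periodic).  In `"frexpan"` mode
#' the acquisition starts with `n_lead_frames` frames recorded before the
#' off-switch beam is enabled, after which frames strictly alternate
#' between a `switch` frame (on-switch pulse plus perpendicular off-switch
#' pulse) and a `readout` frame.
#'
#' @param n_frames total number of camera frames
#' @param frames_per_period_acq camera frames per polarization period at
#'   acquisition (e.g. 30, 60, 100); must be even in `"frexpan"` mode so
#'   that the readout sub-stack has a whole number of frames per period
#' @param mode `"fpm"` (plain, every frame a readout) or `"frexpan"`
#' @param n_lead_frames initial frames without the off-switch beam
#'   (`"frexpan"` only); the remaining `n_frames - n_lead_frames` must be
#'   even
#' @param dose_on dimensionless on-switch dose `a`; the probability that a
#'   fluorophore at angle offset \eqn{\delta} from the on-switch
#'   polarization is switched on is \eqn{1 - e^{-a\cos^2\delta}}
#' @param dose_off dimensionless off-switch dose `b`; surviving the
#'   perpendicular off pulse has probability \eqn{e^{-b\sin^2\delta}}
#' @param switch_brightness emission amplitude of switch frames relative to
#'   `B0` (the off-switch beam drives intense fluorescence; its magnitude
#'   relative to readout is instrument-dependent and exposed here)
#' @param frame_interval_ms wall-clock time between frames, used for the
#'   diffusion step
#' @return an `acquisition_plan`
#' @export
acquisition_plan <- function(n_frames, frames_per_period_acq,
                             mode = c("fpm", "frexpan"),
                             n_lead_frames = 0L, dose_on = 6, dose_off = 3,
                             switch_brightness = 3, frame_interval_ms = 30) {
  mode <- match.arg(mode)
  check_positive(n_frames, "n_frames")
  check_positive(frames_per_period_acq, "frames_per_period_acq")
  if (n_lead_frames < 0 || n_lead_frames >= n_frames)
    stopf("'n_lead_frames' must be in [0, n_frames)")
  if (mode == "frexpan") {
    if ((n_frames - n_lead_frames) %% 2 != 0)
      stopf("frexpan mode needs an even number of frames after the %d lead frames (got %d)",
            n_lead_frames, n_frames - n_lead_frames)
    if (frames_per_period_acq %% 2 != 0)
      stopf("frexpan mode needs an even 'frames_per_period_acq'")
  }
  if (dose_on < 0 || dose_off < 0) stopf("doses must be >= 0")
  structure(list(n_frames = as.integer(n_frames),
                 frames_per_period_acq = as.integer(frames_per_period_acq),
                 mode = mode, n_lead_frames = as.integer(n_lead_frames),
                 dose_on = dose_on, dose_off = dose_off,
                 switch_brightness = switch_brightness,
                 frame_interval_ms = frame_interval_ms),
            class = "acquisition_plan")
}

#' Per-frame pulse roles of a plan
#'
#' @param plan an [acquisition_plan()]
#' @return character vector: `"lead"`, `"switch"` or `"readout"`; in
#'   `"fpm"` mode every frame is a readout
#' @export
frame_roles <- function(plan) {
  if (plan$mode == "fpm") return(rep("readout", plan$n_frames))
  n_rest <- plan$n_frames - plan$n_lead_frames
  c(rep("lead", plan$n_lead_frames),
    rep(c("switch", "readout"), n_rest / 2))
}

#' Excitation polarization angle of a camera frame
#'
#' @param plan an [acquisition_plan()]
#' @param k frame index (1-based), vectorized
#' @return angle(s) in \eqn{[0, \pi)}
#' @export
angle_of_frame <- function(plan, k) {
  mod_pi(pi * (k - 1) / plan$frames_per_period_acq)
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> %s, %d frames (%d lead), %d frames/period, a=%g, b=%g\n",
              x$mode, x$n_frames, x$n_lead_frames, x$frames_per_period_acq,
              x$dose_on, x$dose_off))
  invisible(x)
}

#' Wide-field detector model
#'
#' @param shape image size `c(rows, cols)` in pixels
#' @param pixel_size nm per pixel (default 45, matching 11 x 11-pixel ROIs
#'   spanning 495 x 495 nm)
#' @param psf_sigma Gaussian PSF standard deviation in nm; default
#'   `0.21 * 525 / 1.4` for 525 nm emission through an NA 1.4 objective
#' @param gain camera counts per photon
#' @param offset camera baseline in counts
#' @param read_noise_sd Gaussian read-noise standard deviation in counts
#' @param shot_noise apply Poisson photon noise?
#' @param seed base RNG seed; per-frame streams are derived from it
#' @export
detector_model <- function(shape = c(64L, 64L), pixel_size = 45,
                           psf_sigma = 0.21 * 525 / 1.4, gain = 1,
                           offset = 100, read_noise_sd = 2,
                           shot_noise = TRUE, seed = 1L) {
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_sigma, "psf_sigma")
  check_positive(gain, "gain")
  if (read_noise_sd < 0) stopf("'read_noise_sd' must be >= 0")
  if (length(shape) != 2 || any(shape < 4)) stopf("'shape' must be c(rows, cols), each >= 4")
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 psf_sigma = psf_sigma, gain = gain, offset = offset,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "detector_model")
}

#' A noise-free detector (no shot noise, no read noise, zero offset)
#' @inheritParams detector_model
#' @param ... passed to [detector_model()]
#' @export
ideal_detector <- function(shape = c(64L, 64L), ...) {
  detector_model(shape = shape, offset = 0, read_noise_sd = 0,
                 shot_noise = FALSE, ...)
}
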