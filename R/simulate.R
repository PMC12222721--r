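#' Simulate a polarization-modulated acquisition
#'
#' Renders one camera frame per plan entry.  In `"frexpan"` mode, lead
#' frames and readout frames carry the plain FPM and angle-narrowed
#' emission respectively ([expected_emission()]), while switch frames
#' contain the bright fluorescence driven by the perpendicular off-switch
#' beam (amplitude set by the plan's `switch_brightness`).  Fluorophores
#' diffuse along their membrane between frames
#' (variance `2 * D_lat * frame_interval_ms` per step).
#'
#' Randomness (diffusion, shot noise, read noise) is drawn from a
#' deterministic per-frame stream derived from `det$seed`, so the same
#' (field, plan, detector) triple reproduces the stack bit for bit.
#'
#' @param field a [populate_dipoles()] field
#' @param plan an [acquisition_plan()]
#' @param det a [detector_model()]
#' @param render_method `"integrate"` (exact pixel integrals; reference)
#'   or `"splat"` (bilinear deposit + PSF convolution; fast, for dense
#'   scenes)
#' @param store_truth keep per-frame ground truth (orientations and
#'   expected photons per fluorophore)?
#' @return list with elements `stack` (an [image_stack()] with roles and
#'   angles) and `truth` (parameters, seed, and per-frame ground truth if
#'   requested)
#' @export
simulate_stack <- function(field, plan, det,
                           render_method = c("integrate", "splat"),
                           store_truth = TRUE) {
  render_method <- match.arg(render_method)
  roles <- frame_roles(plan)
  nf <- plan$n_frames
  dat <- array(0, c(nf, det$shape[1], det$shape[2]))
  n <- n_dipoles(field)
  orient <- if (store_truth) matrix(NA_real_, nf, n) else NULL
  ephot <- if (store_truth) matrix(NA_real_, nf, n) else NULL
  for (k in seq_len(nf)) {
    set.seed(frame_seed(det$seed, k))
    alpha <- angle_of_frame(plan, k)
    e <- switch(roles[k],
      lead = expected_emission(field, alpha, "fpm"),
      readout = if (plan$mode == "frexpan")
        expected_emission(field, alpha, "frexpan", plan$dose_on, plan$dose_off)
      else expected_emission(field, alpha, "fpm"),
      switch = switch_emission(field, alpha, plan$switch_brightness))
    dat[k, , ] <- render_frame(dipole_xy(field), e, det,
                               method = render_method)
    if (store_truth) {
      orient[k, ] <- dipole_orientation(field)
      ephot[k, ] <- e
    }
    if (k < nf) field <- step_dipoles(field, plan$frame_interval_ms)
  }
  stack <- image_stack(dat, plan$frames_per_period_acq, det$pixel_size,
                       roles = roles, angles = angle_of_frame(plan, seq_len(nf)))
  truth <- list(plan = plan, detector = det, seed = det$seed,
                field_seed = field$seed, n_dipoles = n,
                c = field$c, anchor_offset = field$anchor_offset,
                B0 = field$B0, D_lat = field$D_lat,
                orientations = orient, expected_photons = ephot)
  list(stack = stack, truth = truth)
}

#' Rasterize the true membrane orientation near each pixel
#'
#' Ground-truth companion to simulated stacks: marks the pixels within
#' `radius_nm` of each contour and records the dipole axis (tangent +
#' `anchor_offset`) there.  Used to score phase maps and phase-sliced
#' reconstructions against the geometry that generated the data.
#'
#' @param geom a [make_geometry()] object
#' @param det a [detector_model()] (pixel grid)
#' @param radius_nm half-width of the membrane band
#' @param anchor_offset angle added to the tangent (default \eqn{\pi/2},
#'   matching [populate_dipoles()])
#' @return list with `phase` (rows x cols, NA off-membrane), `mask`
#'   (logical rows x cols) and `contour_masks` (one logical matrix per
#'   contour)
#' @export
true_orientation_map <- function(geom, det, radius_nm = det$pixel_size,
                                 anchor_offset = pi / 2) {
  nr <- det$shape[1]; nc <- det$shape[2]; px <- det$pixel_size
  phase <- matrix(NA_real_, nr, nc)
  masks <- vector("list", length(geom$contours))
  rpx <- max(1L, round(radius_nm / px))
  brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
  for (j in seq_along(geom$contours)) {
    ct <- geom$contours[[j]]
    s <- seq(0, ct$length, by = px / 2)
    xy <- point_at_s(ct, s)
    ii <- floor(xy[, 2] / px) + 1; jj <- floor(xy[, 1] / px) + 1
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    m <- matrix(0, nr, nc)
    m[cbind(ii[ok], jj[ok])] <- 1
    m <- EBImage::dilate(m, brush) > 0
    masks[[j]] <- m
    ph <- mod_pi(tangent_angle(geom, s, j) + anchor_offset)
    # nearest-sample phase for the band pixels of this contour
    band <- which(m, arr.ind = TRUE)
    if (nrow(band) > 0) {
      cx <- (band[, 2] - 0.5) * px; cy <- (band[, 1] - 0.5) * px
      # chunked nearest neighbour against the dense contour sampling
      idx <- vapply(seq_len(nrow(band)), function(q) {
        which.min((xy[, 1] - cx[q])^2 + (xy[, 2] - cy[q])^2)
      }, integer(1))
      phase[band] <- ph[idx]
    }
  }
  list(phase = phase, mask = Reduce(`|`, masks), contour_masks = masks)
}
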