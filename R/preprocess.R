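#' Per-pixel stack mean normalization
#'
#' Divides every pixel's temporal trace by its own mean over the stack, so
#' each pixel's trace has mean 1 wherever the original mean was positive.
#' This is the "stack mean normalization" background correction of the
#' processing chain; downstream fits operate on dimensionless traces
#' around 1.  Pixels with zero mean are set to 0 and flagged in the
#' `"zero_mask"` attribute.
#'
#' @param stack an [image_stack()]
#' @return normalized [image_stack()] (metadata preserved)
#' @export
mean_normalize <- function(stack) {
  mu <- mean_image(stack)
  if (all(mu == 0)) {
    warning("all-zero stack: returned unchanged")
    return(stack)
  }
  zero <- mu == 0
  mu_safe <- ifelse(zero, 1, mu)
  nf <- n_frames(stack)
  d <- stack$data / rep(mu_safe, each = nf)
  if (any(zero)) d[rep(zero, each = nf)] <- 0
  out <- image_stack(d, stack$frames_per_period, stack$pixel_size,
                     stack$roles, stack$angles)
  attr(out, "zero_mask") <- zero
  out
}

#' Extract the readout frames of a FrExPAN acquisition
#'
#' Drops the first `n_cut` frames (the leads recorded before the
#' off-switch beam was enabled), then keeps only readout-role frames of
#' the remainder, preserving order.  If the stack has no role labels, the
#' frames after the cut are assumed to alternate switch, readout, switch,
#' ... (the FrExPAN convention); an odd remainder is an error.  The
#' readout sub-stack advances two acquisition angle steps per frame, so
#' `frames_per_period` halves.
#'
#' @param stack an [image_stack()] with `frames_per_period` equal to the
#'   acquisition value
#' @param n_cut number of initial frames to drop
#' @return readout-only [image_stack()]
#' @export
demux_frexpan <- function(stack, n_cut) {
  nf <- n_frames(stack)
  if (n_cut < 0 || n_cut >= nf) stopf("'n_cut' must be in [0, %d)", nf)
  rest <- seq(n_cut + 1, nf)
  if (!is.null(stack$roles)) {
    keep <- rest[stack$roles[rest] == "readout"]
  } else {
    if (length(rest) %% 2 != 0)
      stopf("%d frames remain after cutting %d: cannot split switch/readout pairs",
            length(rest), n_cut)
    keep <- rest[seq(2, length(rest), by = 2)]
  }
  out <- image_stack(stack$data[keep, , , drop = FALSE],
                     stack$frames_per_period %/% 2L, stack$pixel_size,
                     roles = stack$roles[keep], angles = stack$angles[keep])
  out
}

#' Periodic average of a modulation stack
#'
#' Compresses a long acquisition into a single polarization period: output
#' frame k is the mean of input frames k, k+N, k+2N, ... over all complete
#' periods.  Trailing frames that do not fill a whole period are dropped.
#'
#' @param stack an [image_stack()]
#' @param N frames per period (default: the stack's `frames_per_period`)
#' @return an N-frame [image_stack()]
#' @export
periodic_average <- function(stack, N = stack$frames_per_period) {
  nf <- n_frames(stack)
  if (nf < N) stopf("stack has %d frames, fewer than one period (%d)", nf, N)
  np <- nf %/% N
  d <- stack$data[seq_len(np * N), , , drop = FALSE]
  dim(d) <- c(N, np, dim(d)[2], dim(d)[3])
  avg <- apply(d, c(1, 3, 4), mean)
  image_stack(avg, N, stack$pixel_size,
              roles = stack$roles[seq_len(N)], angles = stack$angles[seq_len(N)])
}

#' Per-pixel FFT demodulation into offset, amplitude and phase maps
#'
#' For a period stack whose pixel traces follow
#' \eqn{I_k = y_0 + A\cos^2(\pi k/N - x)}, the fundamental DFT bin
#' \eqn{C_1 = \sum_k I_k e^{-2\pi i k/N}} equals \eqn{(AN/4)e^{-2ix}}, so
#' \eqn{A = 4|C_1|/N} and \eqn{x = (-\arg C_1/2) \bmod \pi}.  The offset
#' map is the temporal mean.  The recovery is exact (to rounding) for any
#' noiseless cos-squared trace because such a trace has energy only in the
#' DC and fundamental bins.
#'
#' @param period_stack an [image_stack()], at least 4 frames (the
#'   fundamental is not resolvable below that)
#' @return a `phase_map`: list of `offset`, `amplitude`, `phase` matrices,
#'   a logical `mask` (TRUE where amplitude is exactly zero and the phase,
#'   reported as 0, is meaningless), and `pixel_size`
#' @export
fft_demodulate <- function(period_stack) {
  N <- n_frames(period_stack)
  if (N < 4) stopf("need at least 4 frames per period to resolve the fundamental (got %d)", N)
  d <- period_stack$data
  nr <- dim(d)[2]; nc <- dim(d)[3]
  dim(d) <- c(N, nr * nc)
  ft <- mvfft(d)
  c1 <- ft[2, ]
  # the DFT sees the trace indexed by frame; if the first frame was not
  # acquired at alpha = 0, shift the recovered phase accordingly
  a0 <- if (!is.null(period_stack$angles)) period_stack$angles[1] else 0
  amp <- matrix(4 * Mod(c1) / N, nr, nc)
  phase <- matrix(mod_pi(-Arg(c1) / 2 + a0), nr, nc)
  offset <- matrix(Re(ft[1, ]) / N, nr, nc)
  mask <- amp == 0
  phase[mask] <- 0
  structure(list(offset = offset, amplitude = amp, phase = phase,
                 mask = mask, pixel_size = period_stack$pixel_size),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, amplitude range [%.3g, %.3g]\n",
              nrow(x$amplitude), ncol(x$amplitude),
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' Render a phase map as an RGB image
#'
#' `"hue"` mode maps phase to hue (HSV, saturation 1, \eqn{\pi}-periodic)
#' and modulation amplitude to value, normalized to the maximum amplitude.
#' `"two_color"` assigns red to pixels with phase below `threshold` and
#' green to the rest, with channel intensity proportional to amplitude —
#' the two-color phase coding used to contrast structures of different
#' orientation.
#'
#' @param pm a [fft_demodulate()] phase map
#' @param mode `"hue"` or `"two_color"`
#' @param threshold phase threshold in radians (two_color mode)
#' @return rows x cols x 3 RGB array in \eqn{[0, 1]}
#' @export
phase_color_render <- function(pm, mode = c("hue", "two_color"),
                               threshold = pi / 2) {
  mode <- match.arg(mode)
  amax <- max(pm$amplitude)
  v <- if (amax > 0) pm$amplitude / amax else pm$amplitude
  nr <- nrow(v); nc <- ncol(v)
  rgb <- array(0, c(nr, nc, 3))
  if (mode == "hue") {
    cols <- col2rgb(hsv(h = mod_pi(pm$phase) / pi, s = 1, v = pmin(v, 1))) / 255
    rgb[, , 1] <- matrix(cols[1, ], nr, nc)
    rgb[, , 2] <- matrix(cols[2, ], nr, nc)
    rgb[, , 3] <- matrix(cols[3, ], nr, nc)
  } else {
    below <- mod_pi(pm$phase) < mod_pi(threshold)
    rgb[, , 1] <- ifelse(below, v, 0)
    rgb[, , 2] <- ifelse(below, 0, v)
  }
  rgb
}

#' Persist a phase map (3-page float TIFF) and optional PNG render
#'
#' @param pm a phase map
#' @param path TIFF output path (pages: offset, amplitude, phase)
#' @param png_path optional PNG path for the hue render
#' @export
write_phase_map <- function(pm, path, png_path = NULL) {
  stk <- image_stack(array(c(pm$offset, pm$amplitude, pm$phase),
                           c(nrow(pm$offset), ncol(pm$offset), 3)) |>
                       aperm(c(3, 1, 2)),
                     frames_per_period = 3L, pixel_size = pm$pixel_size)
  write_stack(stk, path, format = "float32")
  if (!is.null(png_path)) png::writePNG(phase_color_render(pm), png_path)
  invisible(path)
}
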