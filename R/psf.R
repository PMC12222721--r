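#' Pixel-integrated Gaussian PSF kernel
#'
#' Discretizes an isotropic 2-D Gaussian by integrating it over each pixel
#' (difference of normal CDFs), truncates at `radius_px` and renormalizes
#' to unit sum.
#'
#' @param sigma_px standard deviation in pixels (> 0)
#' @param radius_px truncation radius in pixels (default `ceiling(4 * sigma)`)
#' @return an odd-sized square matrix summing to 1, with attributes
#'   `sigma_px` and `radius_px`
#' @export
gaussian_psf <- function(sigma_px, radius_px = ceiling(4 * sigma_px)) {
  check_positive(sigma_px, "sigma_px")
  r <- max(1L, as.integer(radius_px))
  edges <- seq(-r - 0.5, r + 0.5, by = 1)
  w <- diff(pnorm(edges / sigma_px))
  k <- outer(w, w)
  k <- k / sum(k)
  structure(k, sigma_px = sigma_px, radius_px = r)
}

# Treat FFT round-off (tiny negative values after convolution) as zero;
# genuinely negative input is a caller error.
clamp_nonneg <- function(d, who) {
  lo <- min(d)
  if (lo < -1e-9 * max(abs(d), 1))
    stopf("%s needs non-negative input", who)
  if (lo < 0) d[d < 0] <- 0
  d
}

# reflective ("mirror") index into 1..n for arbitrary i
mirror_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# 2-D convolution with reflective boundary handling: pad by the kernel
# radius with mirrored pixels, convolve (EBImage::filter2, FFT-based), crop.
conv2_reflect <- function(img, kernel) {
  kr <- (dim(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- mirror_index(seq(1 - kr[1], nr + kr[1]), nr)
  ci <- mirror_index(seq(1 - kr[2], nc + kr[2]), nc)
  padded <- img[ri, ci]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[kr[1] + seq_len(nr), kr[2] + seq_len(nc)]
}
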