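#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update applied to an image, or
#' independently to every frame of a stack:
#' \deqn{u \leftarrow u \cdot \left[K^\ast \ast
#'   \frac{d}{K \ast u}\right],}
#' starting from the data itself.  Convolutions use reflective boundary
#' padding, which keeps flux conservation tight for interior sources.
#' Non-negativity is preserved at every iteration.
#'
#' @param x non-negative matrix or [image_stack()]
#' @param psf a [gaussian_psf()] kernel (any non-negative kernel summing
#'   to 1)
#' @param n_iter iterations (default 500)
#' @param eps small constant guarding the ratio against division by zero
#' @return deconvolved object of the same type as `x`
#' @export
richardson_lucy <- function(x, psf, n_iter = 500L, eps = 1e-12) {
  if (inherits(x, "image_stack")) {
    d <- x$data
    for (k in seq_len(dim(d)[1]))
      d[k, , ] <- rl_one(x$data[k, , ], psf, n_iter, eps)
    out <- x; out$data <- d
    return(out)
  }
  rl_one(x, psf, n_iter, eps)
}

rl_one <- function(d, psf, n_iter, eps) {
  d <- clamp_nonneg(d, "Richardson-Lucy")
  if (all(d == 0)) return(d)
  kflip <- psf[nrow(psf):1, ncol(psf):1]
  u <- d
  for (i in seq_len(n_iter)) {
    ratio <- d / pmax(conv2_reflect(u, psf), eps)
    u <- u * conv2_reflect(ratio, kflip)
  }
  u
}
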