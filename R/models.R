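#' Modulation models of polarization-rotation fluorescence
#'
#' `model_eq1` is the plain FPM response of a (partially) oriented
#' fluorophore population,
#' \deqn{I(\alpha) = y_0 + A\cos^2(\alpha - x),}
#' and `model_eq2` its angle-narrowed counterpart observed with an
#' off-switching (ExPAN) beam,
#' \deqn{I(\alpha) = y_0 + A\,\frac{\cos^2(\alpha - x)}
#'   {1 + f\,\sin^2(\alpha - x)},}
#' where the ExPAN factor `f >= 0` quantifies the narrowing (`f = 0`
#' recovers the plain cos-squared shape; the peak value \eqn{y_0 + A} is
#' unaffected by `f`).
#'
#' @param alpha polarization angle(s), radians
#' @param y0 offset
#' @param A modulation amplitude
#' @param x modulation phase (radians)
#' @param f ExPAN narrowing factor (>= 0)
#' @export
model_eq1 <- function(alpha, y0, A, x) y0 + A * cos(alpha - x)^2

#' @rdname model_eq1
#' @export
model_eq2 <- function(alpha, y0, A, x, f) {
  if (any(f < 0)) stopf("'f' must be >= 0")
  y0 + A * cos(alpha - x)^2 / (1 + f * sin(alpha - x)^2)
}

#' Full width at half maximum of the narrowed modulation term
#'
#' Solving \eqn{\cos^2\Delta/(1 + f\sin^2\Delta) = 1/2} gives
#' \eqn{\cos 2\Delta = f/(2+f)}, hence FWHM
#' \eqn{= \arccos(f/(2+f))} in \eqn{\alpha}: 90 degrees at `f = 0`,
#' 60 degrees at `f = 2`, shrinking towards 0 as `f` grows.
#'
#' @param f ExPAN factor (>= 0)
#' @return FWHM in radians
#' @export
eq2_fwhm <- function(f) {
  if (any(f < 0)) stopf("'f' must be >= 0")
  acos(f / (2 + f))
}

#' Fit a modulation trace with the plain or narrowed model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt,
#' \pkg{minpack.lm}) with `y0 >= 0`, `A >= 0` and `f >= 0` (traces are
#' normalized intensities).  Starting values for `(y0, A, x)` come from
#' the second-harmonic linear regression of the trace (equivalent to the
#' fundamental-bin DFT for evenly spaced angles); `f` starts at 1.  The
#' fit is attempted from the harmonic phase and from that phase plus
#' \eqn{\pi/2}, keeping the solution with the smaller residual sum of
#' squares; the reported phase is reduced to \eqn{[0, \pi)}.
#'
#' @param intensity intensity trace (length >= 5 for eq1, >= 6 for eq2)
#' @param alpha polarization angles; default: evenly spaced over
#'   \eqn{[0, \pi)}
#' @param model `"eq2"` (default) or `"eq1"`
#' @return a `modulation_fit`: `y0`, `A`, `x`, `f` (0 for eq1), `r2`,
#'   `model`, `converged`, `fitted`.  A trace with no variance returns a
#'   flat fit with `A = 0` and `r2 = 0`; a failed fit returns
#'   `converged = FALSE` with `r2 = -Inf` so that quality gates exclude
#'   it.
#' @export
fit_modulation <- function(intensity, alpha = NULL, model = c("eq2", "eq1")) {
  model <- match.arg(model)
  n <- length(intensity)
  if (is.null(alpha)) alpha <- pi * (seq_len(n) - 1) / n
  if (length(alpha) != n) stopf("'alpha' and 'intensity' lengths differ")
  if (n < if (model == "eq2") 6 else 5)
    stopf("need at least %d points to fit %s", if (model == "eq2") 6 else 5, model)
  # the models are pi-periodic: reduce angles to [0, pi) and order them
  # (demultiplexed stacks carry wrapped acquisition angles)
  alpha <- mod_pi(alpha)
  ord <- order(alpha)
  alpha <- alpha[ord]; intensity <- intensity[ord]
  if (any(diff(alpha) <= 0))
    stopf("'alpha' must be distinct modulo pi")

  fit0 <- list(y0 = mean(intensity), A = 0, x = 0, f = 0, r2 = 0,
               model = model, converged = TRUE,
               fitted = rep(mean(intensity), n))
  sst <- sum((intensity - mean(intensity))^2)
  if (sst < 1e-24 * max(1, mean(intensity)^2)) {
    return(structure(fit0, class = "modulation_fit"))
  }

  # harmonic initialisation: I ~ b0 + bc cos(2a) + bs sin(2a)
  h <- coef(lm(intensity ~ cos(2 * alpha) + sin(2 * alpha)))
  A0 <- max(2 * sqrt(h[2]^2 + h[3]^2), 1e-6 * max(abs(intensity)))
  x0 <- mod_pi(atan2(h[3], h[2]) / 2)
  y00 <- max(h[1] - A0 / 2, 0)

  pred <- function(p) {
    if (model == "eq2")
      p[1] + p[2] * cos(alpha - p[3])^2 / (1 + p[4] * sin(alpha - p[3])^2)
    else p[1] + p[2] * cos(alpha - p[3])^2
  }
  one_fit <- function(xs, f0 = 1) {
    par0 <- if (model == "eq2") c(y00, A0, xs, f0) else c(y00, A0, xs)
    lo <- if (model == "eq2") c(0, 0, xs - pi, 0) else c(0, 0, xs - pi)
    hi <- if (model == "eq2") c(Inf, Inf, xs + pi, 1e4) else
      c(Inf, Inf, xs + pi)
    tryCatch(minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                                fn = function(p) intensity - pred(p),
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), list(one_fit(x0), one_fit(x0 + pi / 2),
                                       if (model == "eq2") one_fit(x0, 1e-3)))
  ok <- vapply(fits, function(r) r$info %in% 1:4, logical(1))
  if (!any(ok)) {
    fit0$converged <- FALSE; fit0$r2 <- -Inf
    return(structure(fit0, class = "modulation_fit"))
  }
  fits <- fits[ok]
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  p <- best$par
  out <- list(y0 = p[1], A = p[2], x = mod_pi(p[3]),
              f = if (model == "eq2") p[4] else 0,
              r2 = 1 - min(dev) / sst, model = model,
              converged = TRUE, fitted = pred(p))
  structure(out, class = "modulation_fit")
}

#' @export
print.modulation_fit <- function(x, ...) {
  cat(sprintf("<modulation_fit:%s> y0=%.4g A=%.4g x=%.4g rad f=%.4g R2=%.4f%s\n",
              x$model, x$y0, x$A, x$x, x$f, x$r2,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
as.data.frame.modulation_fit <- function(x, ...) {
  data.frame(y0 = x$y0, A = x$A, x = x$x, f = x$f, r2 = x$r2,
             model = x$model, converged = x$converged)
}
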