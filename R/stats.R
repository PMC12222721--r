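#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled`
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 observations per group")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    stopf("pooled SD is zero with unequal means: d is undefined")
  }
  (mean(x) - mean(y)) / sp
}

#' Compare ExPAN factors between an ExPAN and a NoExPAN stack
#'
#' Fits the narrowed model to each ROI's mean trace in both stacks,
#' applies the two R-squared gates (the NoExPAN gate is lower because
#' plain FPM modulation is weaker), excludes an ROI from both groups if
#' it fails either gate, and summarises the surviving pairs with Cohen's
#' d (pooled SD) and a two-sample independent t-test (Student's by
#' default; set `var_equal = FALSE` for Welch).
#'
#' @param stack_expan,stack_noexpan co-registered periodic-averaged,
#'   normalized stacks sharing the ROI set
#' @param rois a [pick_rois()] result (or data frame with `row`/`col` and
#'   a `roi_size` attribute); only accepted ROIs are used when the column
#'   is present
#' @param r2_gate_expan,r2_gate_noexpan per-stack fit-quality gates
#' @param var_equal Student's (TRUE) or Welch (FALSE) t-test
#' @return an `expan_stats` list: per-ROI factors, group means and SDs,
#'   `cohens_d`, `t_statistic`, `p_value`, `n_rois`
#' @export
compare_expan <- function(stack_expan, stack_noexpan, rois,
                          r2_gate_expan = 0.7, r2_gate_noexpan = 0.4,
                          var_equal = TRUE) {
  if (!is.null(rois$accepted)) rois_use <- rois[rois$accepted, , drop = FALSE]
  else rois_use <- rois
  attr(rois_use, "roi_size") <- attr(rois, "roi_size")
  if (nrow(rois_use) == 0) stopf("no ROIs to compare")
  tr_e <- roi_traces(stack_expan, rois_use)
  tr_n <- roi_traces(stack_noexpan, rois_use)
  fit_row <- function(tr, angles) apply(tr, 1, fit_modulation,
                                        alpha = angles, model = "eq2")
  fits_e <- fit_row(tr_e, stack_expan$angles)
  fits_n <- fit_row(tr_n, stack_noexpan$angles)
  f_e <- vapply(fits_e, `[[`, numeric(1), "f")
  f_n <- vapply(fits_n, `[[`, numeric(1), "f")
  r2_e <- vapply(fits_e, `[[`, numeric(1), "r2")
  r2_n <- vapply(fits_n, `[[`, numeric(1), "r2")
  ok <- is.finite(r2_e) & is.finite(r2_n) &
    r2_e > r2_gate_expan & r2_n > r2_gate_noexpan
  if (sum(ok) < 2)
    stopf("only %d ROI(s) pass both fit-quality gates: too few for statistics",
          sum(ok))
  f_e <- f_e[ok]; f_n <- f_n[ok]
  d <- cohens_d(f_e, f_n)
  tt <- t.test(f_e, f_n, var.equal = var_equal)
  structure(list(f_expan = f_e, f_noexpan = f_n,
                 rois = rois_use[ok, , drop = FALSE],
                 mean_expan = mean(f_e), sd_expan = sd(f_e),
                 mean_noexpan = mean(f_n), sd_noexpan = sd(f_n),
                 cohens_d = d, t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, n_rois = sum(ok),
                 var_equal = var_equal),
            class = "expan_stats")
}

#' @export
print.expan_stats <- function(x, ...) {
  cat(sprintf("<expan_stats> n=%d ROIs\n  f(ExPAN)   = %.3f +/- %.3f\n  f(NoExPAN) = %.3f +/- %.3f\n  Cohen's d = %.3f, t = %.3f, p = %.3g (%s)\n",
              x$n_rois, x$mean_expan, x$sd_expan, x$mean_noexpan,
              x$sd_noexpan, x$cohens_d, x$t_statistic, x$p_value,
              if (x$var_equal) "Student" else "Welch"))
  invisible(x)
}

#' Phase-align modulation traces for plotting
#'
#' Circularly shifts each trace so that its fitted modulation maximum
#' sits at the centre frame, then duplicates the trace over two periods —
#' the standard presentation that makes narrowing visually comparable
#' across ROIs.
#'
#' @param traces n x N matrix (or a single trace) of one-period traces
#' @param fits optional list of [fit_modulation()] results (one per
#'   trace); fitted phases are computed with the eq2 model when absent
#' @param alpha angles of the trace samples (default evenly spaced over
#'   \eqn{[0, \pi)})
#' @return n x 2N matrix of shifted, doubled traces
#' @export
align_phase_for_plot <- function(traces, fits = NULL, alpha = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, 1)
  N <- ncol(traces)
  alpha <- alpha %||% (pi * (seq_len(N) - 1) / N)
  if (is.null(fits))
    fits <- apply(traces, 1, fit_modulation, alpha = alpha, model = "eq2")
  center <- N %/% 2L + 1L
  out <- matrix(NA_real_, nrow(traces), 2L * N)
  for (i in seq_len(nrow(traces))) {
    # sample index whose angle is closest to the fitted phase (mod pi)
    dph <- abs(mod_pi(alpha - fits[[i]]$x + pi / 2) - pi / 2)
    peak <- which.min(dph)
    shifted <- traces[i, mirror_shift(N, peak, center)]
    out[i, ] <- c(shifted, shifted)
  }
  out
}

mirror_shift <- function(N, peak, center) ((seq_len(N) - 1 + peak - center) %% N) + 1
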