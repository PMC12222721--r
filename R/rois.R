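#' Threshold-based foreground segmentation
#'
#' Otsu threshold on an intensity image followed by small-object removal.
#' Serves as the structural gate of the ROI picker: candidate ROIs must
#' touch segmented foreground, keeping the analysis on fluorescing
#' structures rather than background.
#'
#' @param img intensity image (matrix, >= 0)
#' @param min_size connected components smaller than this (pixels) are
#'   discarded
#' @return logical foreground mask
#' @export
segment_foreground <- function(img, min_size = 20L) {
  mx <- max(img)
  if (mx <= min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
  x <- (img - min(img)) / (mx - min(img))
  mask <- x > EBImage::otsu(x, range = c(0, 1))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(img), ncol(img))
}

# Candidate ROI centres on a touching (non-overlapping) grid of
# roi_size x roi_size tiles, ordered centre-out by Chebyshev ring and
# row-major within each ring.
roi_grid <- function(dims, roi_size) {
  h <- roi_size %/% 2L
  c0 <- floor((dims + 1) / 2)
  kmax_r <- (c0[1] - 1 - h) %/% roi_size
  kmax_rp <- (dims[1] - c0[1] - h) %/% roi_size
  kmax_c <- (c0[2] - 1 - h) %/% roi_size
  kmax_cp <- (dims[2] - c0[2] - h) %/% roi_size
  g <- expand.grid(kr = seq(-kmax_r, kmax_rp), kc = seq(-kmax_c, kmax_cp))
  g <- g[order(pmax(abs(g$kr), abs(g$kc)), g$kr, g$kc), ]
  data.frame(row = c0[1] + g$kr * roi_size, col = c0[2] + g$kc * roi_size)
}

#' Mean modulation traces of square ROIs
#'
#' @param stack an [image_stack()] (typically periodic-averaged and
#'   normalized)
#' @param rois data frame with `row`, `col` centres (or a [pick_rois()]
#'   result) and an ROI `size`
#' @param size ROI side length in pixels (odd); default taken from `rois`
#' @return n_roi x N matrix of ROI-mean traces
#' @export
roi_traces <- function(stack, rois, size = NULL) {
  size <- size %||% attr(rois, "roi_size") %||% 11L
  h <- size %/% 2L
  t(vapply(seq_len(nrow(rois)), function(i) {
    r <- rois$row[i]; cc <- rois$col[i]
    apply(stack$data[, (r - h):(r + h), (cc - h):(cc + h), drop = FALSE],
          1, mean)
  }, numeric(n_frames(stack))))
}

#' Automated centre-out ROI picking
#'
#' Walks a grid of touching `roi_size` x `roi_size` tiles from the image
#' centre outwards (Chebyshev rings, row-major within a ring) and accepts
#' a candidate if (1) its mean in the reference intensity image exceeds
#' the `intensity_quantile` of that image, (2) it overlaps the segmented
#' foreground ([segment_foreground()]), and (3) the narrowed-model fit of
#' its mean trace passes the R-squared gate.  Picking stops at `max_n`
#' accepted ROIs or grid exhaustion.  Accepted ROIs are pairwise disjoint
#' by construction.
#'
#' @param period_stack periodic-averaged, normalized [image_stack()] used
#'   for the modulation fits
#' @param intensity_image reference intensity image for the brightness and
#'   segmentation gates (e.g. the temporal mean of the raw stack); default
#'   is the mean image of `period_stack`
#' @param roi_size odd ROI side length in pixels (default 11)
#' @param max_n maximum number of accepted ROIs
#' @param intensity_quantile brightness gate: ROI mean intensity must
#'   exceed this quantile of `intensity_image`
#' @param r2_gate minimum R-squared of the eq2 fit
#' @param min_seg_size passed to [segment_foreground()]
#' @return data frame of evaluated candidates (`row`, `col`, `accepted`,
#'   `reason`, fit parameters for fitted ones) with attributes
#'   `roi_size` and `traces` (accepted ROIs' mean traces)
#' @export
pick_rois <- function(period_stack, intensity_image = NULL, roi_size = 11L,
                      max_n = 120L, intensity_quantile = 0.8,
                      r2_gate = 0.7, min_seg_size = 20L) {
  if (roi_size %% 2 == 0) stopf("'roi_size' must be odd")
  dims <- dim(period_stack)[2:3]
  if (any(roi_size > dims)) stopf("'roi_size' exceeds the image")
  intensity_image <- intensity_image %||% mean_image(period_stack)
  grid <- roi_grid(dims, roi_size)
  thr <- quantile(intensity_image, intensity_quantile, names = FALSE)
  fg <- segment_foreground(intensity_image, min_seg_size)
  h <- roi_size %/% 2L
  n_acc <- 0L
  recs <- vector("list", nrow(grid))
  traces <- list()
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; cc <- grid$col[i]
    rows <- (r - h):(r + h); cols <- (cc - h):(cc + h)
    rec <- data.frame(row = r, col = cc, accepted = FALSE, reason = "",
                      y0 = NA_real_, A = NA_real_, x = NA_real_,
                      f = NA_real_, r2 = NA_real_)
    if (mean(intensity_image[rows, cols]) <= thr) {
      rec$reason <- "intensity"
    } else if (!any(fg[rows, cols])) {
      rec$reason <- "segmentation"
    } else {
      tr <- apply(period_stack$data[, rows, cols, drop = FALSE], 1, mean)
      fit <- fit_modulation(tr, alpha = period_stack$angles, model = "eq2")
      rec$y0 <- fit$y0; rec$A <- fit$A; rec$x <- fit$x
      rec$f <- fit$f; rec$r2 <- fit$r2
      if (is.finite(fit$r2) && fit$r2 > r2_gate) {
        rec$accepted <- TRUE; rec$reason <- "ok"
        n_acc <- n_acc + 1L
        traces[[n_acc]] <- tr
      } else {
        rec$reason <- "r2"
      }
    }
    recs[[i]] <- rec
    if (n_acc >= max_n) break
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  attr(out, "roi_size") <- as.integer(roi_size)
  attr(out, "traces") <- if (n_acc > 0) do.call(rbind, traces) else
    matrix(0, 0, n_frames(period_stack))
  class(out) <- c("roi_set", "data.frame")
  out
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d candidates evaluated, %d accepted (size %d px)\n",
              nrow(x), sum(x$accepted), attr(x, "roi_size")))
  invisible(as.data.frame(x))
}
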