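#' Membrane contour geometries
#'
#' Build a `membrane_geometry`: one or more polyline contours (in nm) on
#' which fluorophores can be placed.  Each contour carries arc-length
#' bookkeeping and per-segment tangent angles; tangents are axes, reported
#' modulo \eqn{\pi}.  For a circle of radius `r`, the tangent at polar
#' angle \eqn{\theta} is \eqn{\theta + \pi/2 \pmod \pi}.
#'
#' @param kind one of `"circle"`, `"segment"`, `"spinehead"`,
#'   `"two_membranes"`, `"crossing_filaments"`, `"vesicles"` (a scene of
#'   several circles, emulating vesicle-rich cytoplasm), or `"cell"` (a
#'   large plasma-membrane circle with vesicles scattered inside).
#' @param ... shape parameters, all lengths in nm:
#'   \describe{
#'     \item{circle}{`r`, `center = c(0, 0)`}
#'     \item{segment}{`length`, `angle = 0`, `center = c(0, 0)`}
#'     \item{spinehead}{`head_radius`, `neck_width`, `neck_length`,
#'       `center` (head centre)}
#'     \item{two_membranes}{`length`, `gap`, `angle = 0`, `center`; two
#'       parallel membranes separated by `gap` (possibly below the PSF
#'       width)}
#'     \item{crossing_filaments}{`angles` (two tangent angles, radians),
#'       `length`, `center`; two straight filaments crossing once}
#'     \item{vesicles}{`n`, `r_range`, `extent = c(w, h)`, `seed`,
#'       `margin`; `n` circles with radii drawn uniformly from `r_range`,
#'       centres placed on a jittered grid inside `extent`}
#'     \item{cell}{`extent`, `r_cell`, `n_vesicles`, `r_range`, `seed`}
#'   }
#' @return an object of class `membrane_geometry` with a list element
#'   `contours`; each contour holds `points` (n x 2 matrix, nm), `closed`,
#'   cumulative arc length and per-segment tangent angles.
#' @examples
#' g <- make_geometry("circle", r = 500)
#' tangent_angle(g, s = pi / 2 * 500) # top of the circle: horizontal tangent
#' @export
make_geometry <- function(kind = c("circle", "segment", "spinehead",
                                   "two_membranes", "crossing_filaments",
                                   "vesicles", "cell"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  contours <- switch(kind,
    circle = {
      r <- p$r %||% stopf("circle needs a radius 'r'")
      check_positive(r, "r")
      list(circle_contour(r, p$center %||% c(0, 0)))
    },
    segment = {
      len <- p$length %||% stopf("segment needs a 'length'")
      check_positive(len, "length")
      list(segment_contour(len, p$angle %||% 0, p$center %||% c(0, 0)))
    },
    spinehead = {
      r <- p$head_radius %||% 250
      w <- p$neck_width %||% 120
      l <- p$neck_length %||% 400
      check_positive(r, "head_radius"); check_positive(w, "neck_width")
      check_positive(l, "neck_length")
      if (w >= 2 * r) stopf("neck_width must be smaller than the head diameter")
      list(spinehead_contour(r, w, l, p$center %||% c(0, 0)))
    },
    two_membranes = {
      len <- p$length %||% stopf("two_membranes needs a 'length'")
      gap <- p$gap %||% stopf("two_membranes needs a 'gap'")
      check_positive(len, "length"); check_positive(gap, "gap")
      ang <- p$angle %||% 0
      ctr <- p$center %||% c(0, 0)
      nrm <- c(-sin(ang), cos(ang)) # unit normal
      list(
        segment_contour(len, ang, ctr + nrm * gap / 2),
        segment_contour(len, ang, ctr - nrm * gap / 2)
      )
    },
    crossing_filaments = {
      angs <- p$angles %||% stopf("crossing_filaments needs two 'angles'")
      if (length(angs) != 2) stopf("crossing_filaments needs exactly two angles")
      len <- p$length %||% stopf("crossing_filaments needs a 'length'")
      check_positive(len, "length")
      ctr <- p$center %||% c(0, 0)
      lapply(angs, function(a) segment_contour(len, a, ctr))
    },
    vesicles = {
      n <- p$n %||% stopf("vesicles needs 'n'")
      rr <- p$r_range %||% stopf("vesicles needs 'r_range'")
      ext <- p$extent %||% stopf("vesicles needs 'extent' (c(width, height) nm)")
      check_positive(n, "n"); check_positive(min(rr), "r_range")
      check_positive(min(ext), "extent")
      vesicle_contours(n, rr, ext, p$margin %||% max(rr) * 1.2,
                       p$seed %||% 1L)
    },
    cell = {
      # a cell-like scene: one large, locally smooth plasma membrane
      # circle plus cytoplasmic vesicles scattered inside it
      ext <- p$extent %||% stopf("cell needs 'extent' (c(width, height) nm)")
      r_cell <- p$r_cell %||% (0.4 * min(ext))
      n <- p$n_vesicles %||% 20
      rr <- p$r_range %||% c(300, 480)
      check_positive(r_cell, "r_cell"); check_positive(n, "n_vesicles")
      check_positive(min(rr), "r_range")
      ctr <- c(ext[1] / 2, ext[2] / 2)
      ves <- vesicle_contours(n, rr, rep(2 * (r_cell - max(rr)) / sqrt(2), 2),
                              max(rr), p$seed %||% 1L)
      # recentre the vesicle grid (built in its own box) into the cell
      shift <- ctr - (r_cell - max(rr)) / sqrt(2)
      ves <- lapply(ves, function(ct) {
        pts <- ct$points
        pts[, 1] <- pts[, 1] + shift[1]; pts[, 2] <- pts[, 2] + shift[2]
        make_contour(pts, ct$closed)
      })
      c(list(circle_contour(r_cell, ctr)), ves)
    }
  )
  structure(list(kind = kind, contours = contours, params = p),
            class = "membrane_geometry")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be positive and finite", name)
  invisible(x)
}

# Build contour bookkeeping from an ordered point list.
make_contour <- function(points, closed) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 3)
  seg_to <- if (closed) rbind(points[-1, , drop = FALSE], points[1, ]) else
    points[-1, , drop = FALSE]
  seg_from <- if (closed) points else points[-nrow(points), , drop = FALSE]
  d <- seg_to - seg_from
  seg_len <- sqrt(rowSums(d^2))
  keep <- seg_len > 0
  d <- d[keep, , drop = FALSE]; seg_len <- seg_len[keep]
  seg_from <- seg_from[keep, , drop = FALSE]
  list(points = points, closed = closed,
       seg_from = seg_from, seg_dir = d / seg_len, seg_len = seg_len,
       s_breaks = c(0, cumsum(seg_len)),
       seg_tan = mod_pi(atan2(d[, 2], d[, 1])),
       length = sum(seg_len))
}

circle_contour <- function(r, center, n = NULL) {
  # vertex count: ~15 nm resolution, rounded to a multiple of 4 so that the
  # cardinal points (theta = 0, pi/2, ...) are vertices
  n <- n %||% max(64, 4 * ceiling(pi * r / 30))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  make_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
               closed = TRUE)
}

segment_contour <- function(len, angle, center) {
  u <- c(cos(angle), sin(angle))
  t <- seq(-len / 2, len / 2, length.out = max(3, ceiling(len / 25) + 1))
  make_contour(cbind(center[1] + t * u[1], center[2] + t * u[2]),
               closed = FALSE)
}

# Mushroom-shaped open contour: a circular head on a rectangular neck.
spinehead_contour <- function(r, w, l, center) {
  th0 <- asin(pmin(1, (w / 2) / r))
  # head arc from (-pi/2 + th0) around the top back to (-pi/2 - th0)
  th <- seq(-pi / 2 + th0, 3 * pi / 2 - th0, length.out = 96)
  head <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  y_neck <- center[2] - r * cos(th0) - l
  left <- cbind(rep(center[1] - w / 2, 8),
                seq(center[2] - r * cos(th0), y_neck, length.out = 8))
  right <- cbind(rep(center[1] + w / 2, 8),
                 seq(y_neck, center[2] - r * cos(th0), length.out = 8))
  make_contour(rbind(right, head, left), closed = FALSE)
}

vesicle_contours <- function(n, r_range, extent, margin, seed) {
  set.seed(seed)
  # jittered grid keeps vesicles spread over the field of view
  k <- ceiling(sqrt(n))
  gx <- (seq_len(k) - 0.5) / k * (extent[1] - 2 * margin) + margin
  gy <- (seq_len(k) - 0.5) / k * (extent[2] - 2 * margin) + margin
  centers <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  cell <- min(extent - 2 * margin) / k
  jit <- cell * 0.25
  radii <- runif(n, min(r_range), max(r_range))
  lapply(seq_len(n), function(i) {
    circle_contour(radii[i],
                   c(centers$x[i] + runif(1, -jit, jit),
                     centers$y[i] + runif(1, -jit, jit)))
  })
}

#' Tangent angle along a contour
#'
#' @param geom a [make_geometry()] object
#' @param s arc-length coordinate(s) in nm (wrapped for closed contours,
#'   clamped for open ones)
#' @param contour contour index
#' @return tangent axis angle(s) in \eqn{[0, \pi)}
#' @export
tangent_angle <- function(geom, s, contour = 1L) {
  ct <- geom$contours[[contour]]
  ct$seg_tan[segment_index(ct, s)]
}

segment_index <- function(ct, s) {
  s <- if (ct$closed) s %% ct$length else pmin(pmax(s, 0), ct$length)
  idx <- findInterval(s, ct$s_breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  pmin(pmax(idx, 1L), length(ct$seg_len))
}

# (x, y) nm position at arc-length s on a contour, vectorized over s
point_at_s <- function(ct, s) {
  s <- if (ct$closed) s %% ct$length else pmin(pmax(s, 0), ct$length)
  idx <- segment_index(ct, s)
  ds <- s - ct$s_breaks[idx]
  ct$seg_from[idx, , drop = FALSE] + ct$seg_dir[idx, , drop = FALSE] * ds
}

#' @export
print.membrane_geometry <- function(x, ...) {
  lens <- vapply(x$contours, function(ct) ct$length, numeric(1))
  cat(sprintf("<membrane_geometry> kind=%s, %d contour(s), total length %.2f um\n",
              x$kind, length(x$contours), sum(lens) / 1000))
  invisible(x)
}
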