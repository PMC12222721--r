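#' Multi-frame image stack
#'
#' Container for an acquisition or a processed product: a
#' frames x rows x cols array plus the metadata the analysis chain needs
#' (frames per polarization period, pixel size, optional per-frame roles
#' and polarization angles).
#'
#' @param data numeric array, dim = c(frames, rows, cols), finite values
#' @param frames_per_period camera frames per polarization period of this
#'   stack (after demultiplexing this is half the acquisition value)
#' @param pixel_size nm per pixel
#' @param roles optional per-frame labels (`"lead"`, `"switch"`,
#'   `"readout"`)
#' @param angles optional per-frame polarization angles in \eqn{[0, \pi)}
#' @export
image_stack <- function(data, frames_per_period, pixel_size = 45,
                        roles = NULL, angles = NULL) {
  if (length(dim(data)) != 3) stopf("'data' must be frames x rows x cols")
  if (any(!is.finite(data))) stopf("stack contains non-finite values")
  nf <- dim(data)[1]
  if (!is.null(roles) && length(roles) != nf)
    stopf("'roles' must have one entry per frame")
  if (!is.null(angles) && length(angles) != nf)
    stopf("'angles' must have one entry per frame")
  structure(list(data = data, frames_per_period = as.integer(frames_per_period),
                 pixel_size = pixel_size, roles = roles, angles = angles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.0f nm/px), %d frames/period\n",
              d[1], d[2], d[3], x$pixel_size, x$frames_per_period))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack an [image_stack()]
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Temporal mean image of a stack
#' @param stack an [image_stack()]
#' @return rows x cols matrix
#' @export
mean_image <- function(stack) apply(stack$data, c(2, 3), mean)

#' Write / read image stacks as multi-page TIFF with a JSON sidecar
#'
#' Stacks are stored one frame per TIFF page in time order.  `format
#' = "uint16"` stores rounded counts (clipped to 0..65535); `"float32"`
#' stores values scaled by the stack maximum (scale recorded in the
#' sidecar).  The sidecar `<path>.json` carries frames_per_period,
#' pixel_size, roles, angles, the storage scale and format, so that
#' `read_stack(write_stack(x, p))` reproduces the stack and metadata (to
#' single-float precision for `"float32"`).
#'
#' @param stack an [image_stack()]
#' @param path output TIFF path
#' @param format `"auto"` (uint16 for integer-valued data in range, else
#'   float32), `"uint16"` or `"float32"`
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, format = c("auto", "uint16", "float32")) {
  format <- match.arg(format)
  d <- stack$data
  if (format == "auto") {
    intlike <- max(abs(d - round(d))) < 1e-9 && min(d) >= 0 && max(d) <= 65535
    format <- if (intlike) "uint16" else "float32"
  }
  nf <- dim(d)[1]
  pages <- lapply(seq_len(nf), function(k) d[k, , ])
  if (format == "uint16") {
    scale <- 65535
    pages <- lapply(pages, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    scale <- max(abs(d), 1e-300)
    pages <- lapply(pages, function(m) m / scale)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                     reduce = FALSE))
  }
  meta <- list(frames_per_period = stack$frames_per_period,
               pixel_size = stack$pixel_size, roles = stack$roles,
               angles = stack$angles, scale = scale, format = format)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("not a readable TIFF: %s (%s)",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(frames_per_period = length(pages), pixel_size = 45,
                    scale = 1, format = "float32")
  scale <- if (meta$format == "uint16") 65535 else meta$scale
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  d <- array(0, c(length(pages), nr, nc))
  for (k in seq_along(pages)) d[k, , ] <- pages[[k]] * scale
  if (meta$format == "uint16") d <- round(d)
  image_stack(d, meta$frames_per_period, meta$pixel_size,
              roles = meta$roles %||% NULL,
              angles = meta$angles %||% NULL)
}
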