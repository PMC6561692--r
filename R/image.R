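#' Calibrated grayscale section image
#'
#' A `section_image` wraps a numeric matrix of gray values together with its
#' physical calibration. Rows run dorsal to ventral (y downwards), columns
#' medial to lateral (x rightwards). The physical coordinate of the center of
#' pixel `(row, col)` is `origin + (col - 0.5, row - 0.5) * pixel_size_um`.
#'
#' @param data numeric matrix of gray values.
#' @param pixel_size_um physical pixel pitch in micrometers.
#' @param origin length-2 numeric, physical (x, y) of the top-left image
#'   corner in micrometers.
#' @param stain free-text stain label (e.g. `"BDA-DAB"`, `"Iba1-DAB"`).
#' @param polarity `"dark"` if stained structures are darker than background
#'   (DAB), `"bright"` otherwise.
#' @param frame `"source"` for raw scans, `"template"` once registered into
#'   the template coordinate frame.
#' @param meta named list of free metadata (animal, level, section id).
#' @return object of class `section_image`.
#' @export
section_image <- function(data, pixel_size_um, origin = c(0, 0),
                          stain = "unknown", polarity = c("dark", "bright"),
                          frame = c("source", "template"), meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stopf("`pixel_size_um` must be a positive scalar")
  polarity <- match.arg(polarity)
  frame <- match.arg(frame)
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         origin = as.numeric(origin[1:2]), stain = stain,
         polarity = polarity, frame = frame, meta = meta),
    class = "section_image")
}

#' @export
as.matrix.section_image <- function(x, ...) x$data

#' @export
dim.section_image <- function(x) dim(x$data)

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> %d x %d px @ %.3g um/px, %s frame, %s (%s)\n",
    nrow(x$data), ncol(x$data), x$pixel_size_um, x$frame, x$stain,
    x$polarity))
  invisible(x)
}

## physical (x, y) um -> fractional (row, col); vectorized
um_to_rc <- function(img, x, y) {
  list(row = (y - img$origin[2]) / img$pixel_size_um + 0.5,
       col = (x - img$origin[1]) / img$pixel_size_um + 0.5)
}

rc_to_um <- function(img, row, col) {
  list(x = img$origin[1] + (col - 0.5) * img$pixel_size_um,
       y = img$origin[2] + (row - 0.5) * img$pixel_size_um)
}

#' Sample a gray-value profile along a straight segment
#'
#' Values are sampled by bilinear interpolation at a fixed step (default one
#' pixel pitch), the granularity of gray-scale densitometry along grid lines.
#'
#' @param img a [section_image].
#' @param p0,p1 segment endpoints, physical (x, y) in micrometers.
#' @param step_um sampling step; defaults to the image pixel pitch.
#' @return list with `values`, `t_um` (distance along the segment), and the
#'   sampled `x`/`y` coordinates.
#' @export
sample_profile <- function(img, p0, p1, step_um = NULL) {
  step_um <- step_um %||% img$pixel_size_um
  if (step_um <= 0) stopf("`step_um` must be positive")
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, floor(len / step_um) + 1L)
  t <- seq(0, len, length.out = n)
  x <- p0[1] + (p1[1] - p0[1]) * t / len
  y <- p0[2] + (p1[2] - p0[2]) * t / len
  rc <- um_to_rc(img, x, y)
  v <- bilinear_sample(img$data, rc$row, rc$col)
  list(values = v, t_um = t, x = x, y = y)
}

#' Read / write calibrated TIFF section images
#'
#' Thin wrappers around the `tiff` package storing gray values as 16-bit.
#' Calibration is not part of baseline TIFF; it is supplied by the caller.
#'
#' @param path file path.
#' @param img a [section_image]; gray values are scaled to `[0, 1]` by
#'   `max_gray` on write and scaled back on read.
#' @param max_gray full-scale gray value (default 255).
#' @inheritParams section_image
#' @return `read_section_tiff` returns a [section_image].
#' @export
write_section_tiff <- function(img, path, max_gray = 255) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF i/o")
  m <- clamp(img$data / max_gray, 0, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path, pixel_size_um, origin = c(0, 0),
                              max_gray = 255, ...) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF i/o")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  section_image(m * max_gray, pixel_size_um, origin = origin, ...)
}
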