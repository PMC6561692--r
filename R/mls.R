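#' Fit an affine moving-least-squares deformation from landmark pairs
#'
#' Computes the landmark-interpolating moving-least-squares (MLS)
#' deformation used to fit sections into the GM template. For an evaluation
#' point p, every landmark pair (s_i, d_i) receives weight
#' `w_i = 1 / |p - s_i|^(2*alpha)` and the best weighted affine map of the
#' source landmarks onto the destination landmarks is applied to p. The map
#' is exact at the landmarks (the weight diverges there), smooth elsewhere,
#' and reproduces any global affine transform of the landmarks exactly.
#'
#' @param src,dst n x 2 matrices of corresponding landmark coordinates
#'   (same units, typically 5 landmarks in physical micrometers). `src`
#'   must not be collinear.
#' @param alpha weight falloff exponent (default 1).
#' @return an object of class `deformation_field`; apply it to points with
#'   [mls_apply()] or `predict()`.
#' @examples
#' src <- cbind(c(0, 100, 100, 0, 50), c(0, 0, 100, 100, 50))
#' dst <- src + 10            # pure translation
#' f <- fit_mls(src, dst)
#' mls_apply(f, cbind(25, 70))
#' @export
fit_mls <- function(src, dst, alpha = 1) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!identical(dim(src), dim(dst)) || ncol(src) != 2L)
    stopf("`src` and `dst` must be n x 2 matrices of equal size")
  if (nrow(src) < 3L) stopf("at least 3 landmark pairs are required")
  if (anyDuplicated(src) > 0L) stopf("source landmarks must be distinct")
  if (!is.numeric(alpha) || alpha <= 0) stopf("`alpha` must be positive")
  ctr <- sweep(src, 2, colMeans(src))
  sv <- svd(ctr)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1))
    stopf("degenerate configuration: source landmarks are collinear")
  structure(list(src = src, dst = dst, alpha = alpha),
            class = "deformation_field")
}

#' Evaluate a moving-least-squares deformation at points
#'
#' @param field a `deformation_field` from [fit_mls()].
#' @param pts m x 2 matrix of points to map (same units as the landmarks).
#' @return m x 2 matrix of mapped points. Points coinciding with a source
#'   landmark map to its destination exactly.
#' @export
mls_apply <- function(field, pts) {
  pts <- rbind(pts)
  stopifnot(ncol(pts) == 2L)
  m <- nrow(pts); n <- nrow(field$src)
  s <- field$src; d <- field$dst; a <- field$alpha

  d2 <- matrix(0, m, n)               # squared distances point x landmark
  for (i in seq_len(n))
    d2[, i] <- (pts[, 1] - s[i, 1])^2 + (pts[, 2] - s[i, 2])^2
  snap <- d2 < 1e-12                  # on-landmark points: exact by limit
  w <- 1 / pmax(d2, 1e-12)^a
  wsum <- rowSums(w)
  psx <- (w %*% s[, 1]) / wsum; psy <- (w %*% s[, 2]) / wsum
  qsx <- (w %*% d[, 1]) / wsum; qsy <- (w %*% d[, 2]) / wsum

  # per-point 2x2 normal matrix A = sum_i w_i shat_i shat_i^T and
  # B = sum_i w_i shat_i qhat_i^T, accumulated over landmarks
  a11 <- a12 <- a22 <- b11 <- b12 <- b21 <- b22 <- numeric(m)
  for (i in seq_len(n)) {
    sx <- s[i, 1] - psx; sy <- s[i, 2] - psy
    qx <- d[i, 1] - qsx; qy <- d[i, 2] - qsy
    wi <- w[, i]
    a11 <- a11 + wi * sx * sx
    a12 <- a12 + wi * sx * sy
    a22 <- a22 + wi * sy * sy
    b11 <- b11 + wi * sx * qx
    b12 <- b12 + wi * sx * qy
    b21 <- b21 + wi * sy * qx
    b22 <- b22 + wi * sy * qy
  }
  det <- a11 * a22 - a12 * a12
  det[det == 0] <- NA_real_
  # M = A^-1 B, f(p) = (p - pstar) M + qstar
  m11 <- (a22 * b11 - a12 * b21) / det
  m21 <- (a11 * b21 - a12 * b11) / det
  m12 <- (a22 * b12 - a12 * b22) / det
  m22 <- (a11 * b22 - a12 * b12) / det
  vx <- pts[, 1] - psx; vy <- pts[, 2] - psy
  out <- cbind(drop(qsx) + vx * m11 + vy * m21,
               drop(qsy) + vx * m12 + vy * m22)

  hit <- which(rowSums(snap) > 0L)
  for (j in hit) out[j, ] <- d[which(snap[j, ])[1L], ]
  out
}

#' @export
predict.deformation_field <- function(object, pts, ...) mls_apply(object, pts)

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> affine MLS, %d landmarks, alpha = %g\n",
              nrow(x$src), x$alpha))
  invisible(x)
}

#' Invert a deformation field
#'
#' Returns the MLS field fitted with source and destination landmarks
#' swapped. For landmark sets related by a global affine transform this is
#' the exact inverse; in general it is the standard landmark-consistent
#' approximation used for inverse-mapping resampling.
#'
#' @param field a `deformation_field`.
#' @export
invert_field <- function(field) fit_mls(field$dst, field$src, field$alpha)

#' Warp a section image into the template frame
#'
#' Resamples a source-frame image onto the template raster by inverse
#' mapping: each template pixel center is sent through the inverse
#' deformation into source physical coordinates and sampled there. Bilinear
#' interpolation never produces values outside the input range; use
#' `interpolation = "nearest"` for label/mask images so categories stay
#' categorical.
#'
#' @param image a [section_image] in the source frame.
#' @param field a `deformation_field` mapping source physical coordinates to
#'   template physical coordinates (from [fit_mls()] on the section
#'   landmarks vs the template anchors).
#' @param template a [gm_template]; defines the output raster.
#' @param fill value for output pixels that map outside the source image
#'   (default `NA`, reported in the `coverage` mask).
#' @param interpolation `"bilinear"` (gray values) or `"nearest"` (labels).
#' @return a [section_image] in the template frame; attribute `coverage` is
#'   the logical matrix of pixels that mapped inside the source.
#' @export
warp_section <- function(image, field, template, fill = NA_real_,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(image, "section_image")) stopf("`image` must be a section_image")
  if (!inherits(field, "deformation_field")) stopf("`field` must be a deformation_field")
  inv <- invert_field(field)
  d <- frame_dims(template)
  ps <- template$pixel_size_um
  cx <- template$frame_xlim[1] + (seq_len(d["ncol"]) - 0.5) * ps
  cy <- template$frame_ylim[1] + (seq_len(d["nrow"]) - 0.5) * ps
  gx <- rep(cx, each = d["nrow"])
  gy <- rep(cy, times = d["ncol"])
  srcpts <- mls_apply(inv, cbind(gx, gy))
  rc <- um_to_rc(image, srcpts[, 1], srcpts[, 2])
  v <- if (interpolation == "bilinear")
    bilinear_sample(image$data, rc$row, rc$col)
  else nearest_sample(image$data, rc$row, rc$col)
  cov <- matrix(!is.na(v), d["nrow"], d["ncol"])
  v[is.na(v)] <- fill
  out <- section_image(matrix(v, d["nrow"], d["ncol"]), ps,
                       origin = c(template$frame_xlim[1],
                                  template$frame_ylim[1]),
                       stain = image$stain, polarity = image$polarity,
                       frame = "template", meta = image$meta)
  attr(out, "coverage") <- cov
  out
}

#' Convert pixel landmarks to physical coordinates
#'
#' Landmark tables are recorded as 0-based `row`/`col` pixel positions of
#' the top-left-origin image raster; physical coordinates place the center
#' of pixel (0, 0) at `origin + pixel_size/2`.
#'
#' @param row,col 0-based pixel coordinates.
#' @param pixel_size_um pixel pitch.
#' @param origin physical (x, y) of the image top-left corner.
#' @return n x 2 matrix of (x, y) micrometers.
#' @export
landmarks_px_to_um <- function(row, col, pixel_size_um, origin = c(0, 0)) {
  cbind(origin[1] + (col + 0.5) * pixel_size_um,
        origin[2] + (row + 0.5) * pixel_size_um)
}

#' Read a landmark table
#'
#' CSV with columns `section_id, point_index, row, col` (pixels, 0-based,
#' origin top-left). Returns one 5 x 2 pixel matrix per section, ordered by
#' `point_index`.
#'
#' @param path CSV path.
#' @return named list of 5 x 2 matrices with columns `row`, `col`.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "point_index", "row", "col")
  if (!all(need %in% names(df)))
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$section_id), function(s) {
    s <- s[order(s$point_index), ]
    if (nrow(s) != 5L)
      stopf("section %s: expected exactly 5 landmarks, got %d",
            s$section_id[1], nrow(s))
    m <- cbind(row = s$row, col = s$col)
    if (anyDuplicated(m)) stopf("section %s: coincident landmarks",
                                s$section_id[1])
    m
  })
  out
}
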