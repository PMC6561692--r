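#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rnbinom sd pt p.adjust hclust cutree dist
#' @importFrom utils read.csv write.csv read.delim
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinear interpolation of a matrix at fractional row/column positions
#'
#' Rows and columns are 1-based pixel-center coordinates, so `(1, 1)` is the
#' center of the top-left pixel. Positions outside the matrix (beyond half a
#' pixel past the border) return `fill`.
#'
#' @param mat numeric matrix.
#' @param row,col numeric vectors of equal length.
#' @param fill value returned outside the matrix domain.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(mat, row, col, fill = NA_real_) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(as.numeric(fill), length(row))
  # clamp the half-pixel margin so border-line samples stay defined
  r <- clamp(row, 1, nr)
  c <- clamp(col, 1, nc)
  ok <- row >= 0.5 & row <= nr + 0.5 & col >= 0.5 & col <= nc + 0.5 &
    is.finite(row) & is.finite(col)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- clamp(r0, 1, nr - 1); c0 <- clamp(c0, 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  v <- (1 - fr) * (1 - fc) * mat[i00] + fr * (1 - fc) * mat[i10] +
    (1 - fr) * fc * mat[i01] + fr * fc * mat[i11]
  out[ok] <- v[ok]
  out
}

nearest_sample <- function(mat, row, col, fill = NA_real_) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(as.numeric(fill), length(row))
  r <- round(row); c <- round(col)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  out[ok] <- mat[cbind(r[ok], c[ok])]
  out
}
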