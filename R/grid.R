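#' Build the 20 x 20 sampling grid anchored to the template
#'
#' Constructs the template-frame sampling grid used for fiber densitometry:
#' `n` equispaced vertical lines anchored at the midline side (line 1 on the
#' medial GM extreme) running to the lateral GM extreme, and `n` equispaced
#' horizontal lines anchored at the ventral GM-WM border (line 1 on the
#' ventral GM extreme) running to the dorsal extreme. Panel (i, j) is
#' bounded by vertical lines i, i+1 and horizontal lines j, j+1 (the 21st
#' bounds being the GM extremes); its count collects crossings on its medial
#' vertical edge and its ventral horizontal edge, so every crossing belongs
#' to exactly one panel. Each line carries the interval where it intersects
#' the GM polygon; profiles are clipped to it.
#'
#' @param template a [gm_template].
#' @param n grid dimension (default 20).
#' @return object of class `sampling_grid`.
#' @export
build_grid <- function(template, n = 20L) {
  bb <- gm_bbox(template)
  W <- diff(bb$xlim); H <- diff(bb$ylim)
  if (W <= 0 || H <= 0) stopf("degenerate GM polygon")
  dx <- W / n; dy <- H / n
  v_x <- bb$xlim[1] + (seq_len(n) - 1L) * dx
  h_y <- bb$ylim[2] - (seq_len(n) - 1L) * dy
  v_span <- t(vapply(v_x, function(c)
    line_gm_span(template, "v", c), numeric(2)))
  h_span <- t(vapply(h_y, function(c)
    line_gm_span(template, "h", c), numeric(2)))
  structure(
    list(n = as.integer(n), v_x = v_x, h_y = h_y, v_span = v_span,
         h_span = h_span, dx = dx, dy = dy,
         x0 = bb$xlim[1], x1 = bb$xlim[2],
         y0 = bb$ylim[1], y1 = bb$ylim[2]),
    class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf(
    "<sampling_grid> %d x %d panels, dx = %.4g um, dy = %.4g um\n",
    x$n, x$n, x$dx, x$dy))
  invisible(x)
}

## intersection interval of a vertical ("v", x = c) or horizontal
## ("h", y = c) line with the GM polygon: [min, max] span of the boundary
## crossings. The packaged templates are convex, so the span is the
## GM-clipped segment.
line_gm_span <- function(template, type, c) {
  poly <- template$gm_polygon
  k <- nrow(poly)
  ax <- if (type == "v") poly[, 1] else poly[, 2]  # coord tested against c
  oth <- if (type == "v") poly[, 2] else poly[, 1] # coord collected
  hits <- numeric(0)
  for (i in seq_len(k - 1L)) {
    a1 <- ax[i]; a2 <- ax[i + 1L]
    if (a1 == c && a2 == c) {                      # edge lies on the line
      hits <- c(hits, oth[i], oth[i + 1L])
    } else if ((a1 - c) * (a2 - c) <= 0 && a1 != a2) {
      t <- (c - a1) / (a2 - a1)
      hits <- c(hits, oth[i] + t * (oth[i + 1L] - oth[i]))
    }
  }
  if (length(hits) == 0L) return(c(NA_real_, NA_real_))
  range(hits)
}

grid_lines <- function(grid) {
  rbind(
    data.frame(type = "v", index = seq_len(grid$n), at = grid$v_x,
               from = grid$v_span[, 1], to = grid$v_span[, 2]),
    data.frame(type = "h", index = seq_len(grid$n), at = grid$h_y,
               from = grid$h_span[, 1], to = grid$h_span[, 2]))
}

line_label <- function(type, index) paste0(type, index)

#' Assign grid-line crossings to panels
#'
#' A crossing on vertical line i at dorsoventral position y belongs to
#' panel column i and to the row of the horizontal band containing y
#' (counted from the ventral anchor); a crossing on horizontal line j at
#' mediolateral position x belongs to panel row j and the column of the
#' vertical band containing x. Positions beyond the outer bound are clamped
#' into the outermost panel.
#'
#' @param grid a `sampling_grid`.
#' @param type `"v"` or `"h"`, vectorized.
#' @param index line index 1..n, vectorized.
#' @param pos crossing position along the line (y for vertical lines, x for
#'   horizontal ones), micrometers.
#' @return data.frame with `panel_row`, `panel_col`.
#' @export
assign_panel <- function(grid, type, index, pos) {
  n <- grid$n
  row <- integer(length(pos)); col <- integer(length(pos))
  isv <- type == "v"
  col[isv] <- index[isv]
  row[isv] <- clamp(floor((grid$y1 - pos[isv]) / grid$dy) + 1L, 1L, n)
  row[!isv] <- index[!isv]
  col[!isv] <- clamp(floor((pos[!isv] - grid$x0) / grid$dx) + 1L, 1L, n)
  data.frame(panel_row = row, panel_col = col)
}

## 20x20 zero matrix with panel dimnames: rows = ventral..dorsal bands,
## cols = medial..lateral bands
empty_panel_matrix <- function(n) {
  matrix(0, n, n, dimnames = list(paste0("row", seq_len(n)),
                                  paste0("col", seq_len(n))))
}

panel_centers <- function(grid) {
  i <- rep(seq_len(grid$n), each = grid$n)   # column (medial band)
  j <- rep(seq_len(grid$n), times = grid$n)  # row (ventral band)
  data.frame(panel_row = j, panel_col = i,
             x = grid$x0 + (i - 0.5) * grid$dx,
             y = grid$y1 - (j - 0.5) * grid$dy)
}
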