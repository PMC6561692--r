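# Independent oracles used across the suite. Each reimplements a
# definition naively, without sharing code with the package internals.

# h-minima count by naive morphological reconstruction by erosion
# (pointwise fixpoint of max(f, erosion(marker)) with marker = f + h)
# followed by an exhaustive regional-minima plateau scan; the degenerate
# plateau spanning the whole profile is no event.
hmin_oracle <- function(x, h) {
  n <- length(x)
  if (n == 1L) return(0L)
  R <- x + h
  repeat {
    Rnew <- pmax(x, pmin(R, c(Inf, R[-n]), c(R[-1], Inf)))
    if (identical(Rnew, R)) break
    R <- Rnew
  }
  comps <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && R[j + 1L] == R[i]) j <- j + 1L
    left_ok <- i == 1L || R[i - 1L] > R[i]
    right_ok <- j == n || R[j + 1L] > R[i]
    if (left_ok && right_ok && !(i == 1L && j == n)) comps <- comps + 1L
    i <- j + 1L
  }
  comps
}

# brute-force count of transversal crossings of a polyline with one grid
# line, clipped to the line's GM span (closed interval)
path_line_crossings <- function(path, type, at, span) {
  cnt <- 0L
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    d1 <- if (type == "v") a[1] - at else a[2] - at
    d2 <- if (type == "v") b[1] - at else b[2] - at
    if (d1 * d2 < 0) {
      t <- d1 / (d1 - d2)
      pos <- if (type == "v") a[2] + t * (b[2] - a[2])
             else a[1] + t * (b[1] - a[1])
      if (!is.na(span[1]) && pos >= span[1] && pos <= span[2])
        cnt <- cnt + 1L
    }
  }
  cnt
}

# per-line brute-force crossing counts of a whole fiber set
truth_counts_oracle <- function(paths, grid) {
  gl <- cordmap:::grid_lines(grid)
  out <- stats::setNames(integer(nrow(gl)),
                         paste0(gl$type, gl$index))
  for (i in seq_len(nrow(gl))) {
    li <- gl[i, ]
    out[i] <- sum(vapply(paths, path_line_crossings, integer(1),
                         type = li$type, at = li$at,
                         span = c(li$from, li$to)))
  }
  out
}

# Benjamini-Hochberg by definition: the step-up FDR of p_i is the
# smallest m * t / #{p <= t} over candidate thresholds t >= p_i
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi - 1e-15]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# integer-pixel shift between two equal-size images by the peak of their
# fft cross-correlation (phase-correlation oracle for translations)
xcorr_shift <- function(a, b) {
  A <- stats::fft(a); B <- stats::fft(b)
  r <- Re(stats::fft(Conj(A) * B, inverse = TRUE))
  idx <- which(r == max(r), arr.ind = TRUE)[1, ] - 1L
  d <- dim(a)
  ifelse(idx > d / 2, idx - d, idx)   # (row shift, col shift)
}

# do the selected cells put >= k in each quadrant of the given bbox?
quadrants_covered <- function(x, y, xlim, ylim, k = 2) {
  qx <- x > mean(xlim); qy <- y > mean(ylim)
  tab <- table(factor(paste(qx, qy),
                      levels = c("FALSE FALSE", "FALSE TRUE",
                                 "TRUE FALSE", "TRUE TRUE")))
  all(tab >= k)
}

# uniform random cells inside the GM polygon of a template
uniform_gm_cells <- function(template, n, seed = 99) {
  set.seed(seed)
  bb <- cordmap:::gm_bbox(template)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    x <- runif(2 * n, bb$xlim[1], bb$xlim[2])
    y <- runif(2 * n, bb$ylim[1], bb$ylim[2])
    ok <- point_in_gm(template, x, y)
    out <- rbind(out, data.frame(x_um = x[ok], y_um = y[ok]))
  }
  out[seq_len(n), ]
}

# shared small fixtures (built once per test run)
tpl_hemi <- hemicord_template()
grid_hemi <- build_grid(tpl_hemi)
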