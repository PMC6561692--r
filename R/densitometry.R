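#' Derive a probe-specific intensity threshold from sampled images
#'
#' In situ signal fractions use gene-specific thresholds defined on
#' `n_pick` randomly selected images of the dataset and averaged. The
#' default per-image rule is Otsu's bimodal split.
#'
#' @param images list of numeric matrices (or [section_image]s).
#' @param picker per-image threshold rule, a function of a matrix returning
#'   a scalar; default [otsu_threshold()].
#' @param n_pick number of images to sample (default 5).
#' @param seed integer seed for the image draw.
#' @return object of class `threshold_spec`: `threshold` (the average),
#'   `per_image` thresholds and the `picked` image indices.
#' @export
derive_threshold <- function(images, picker = otsu_threshold, n_pick = 5,
                             seed = 1) {
  if (length(images) < n_pick)
    stopf("need at least %d images, got %d", n_pick, length(images))
  set.seed(as.integer(seed))
  picked <- sort(sample(length(images), n_pick))
  ths <- vapply(images[picked], function(im) {
    m <- if (inherits(im, "section_image")) im$data else as.matrix(im)
    picker(m)
  }, numeric(1))
  structure(list(threshold = mean(ths), per_image = ths, picked = picked),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %.6g (mean of %d image thresholds)\n",
              x$threshold, length(x$per_image)))
  invisible(x)
}

#' Otsu threshold of a gray-value matrix
#'
#' Wraps `EBImage::otsu` over the matrix's own intensity range.
#'
#' @param mat numeric matrix.
#' @param levels histogram resolution (default 256).
#' @return scalar threshold on the matrix's intensity scale.
#' @export
otsu_threshold <- function(mat, levels = 256) {
  r <- range(mat)
  if (diff(r) == 0) return(r[1])
  as.numeric(EBImage::otsu(EBImage::Image(mat), range = r,
                           levels = levels))
}

#' Suprathreshold signal fraction within a region
#'
#' Percentage of region pixels whose value exceeds the threshold — the
#' percentage of white signal over black background in a defined region.
#' For dark-signal stains use `polarity = "dark"`, which counts
#' subthreshold pixels instead.
#'
#' @param image numeric matrix or [section_image].
#' @param region_mask logical matrix, non-empty.
#' @param threshold intensity threshold (scalar or `threshold_spec`).
#' @param polarity `"bright"` (default) if signal is brighter than
#'   background.
#' @return percentage in `[0, 100]`.
#' @export
signal_fraction <- function(image, region_mask, threshold,
                            polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  m <- if (inherits(image, "section_image")) image$data else as.matrix(image)
  if (inherits(threshold, "threshold_spec")) threshold <- threshold$threshold
  region_mask <- as.logical(region_mask)
  if (!any(region_mask)) stopf("empty region mask")
  v <- m[region_mask]
  hit <- if (polarity == "bright") v > threshold else v < threshold
  100 * sum(hit) / length(v)
}

#' Lesion completeness from CST signal
#'
#' Percentage of CST marker signal in the stroke-denervated dorsal
#' funiculus relative to the healthy side of the same section; a complete
#' lesion approaches 0%.
#'
#' @param lesioned_cst_signal,healthy_cst_signal summed or mean marker
#'   signal of the lesioned and healthy CST areas (healthy > 0).
#' @return percentage.
#' @export
cst_completeness <- function(lesioned_cst_signal, healthy_cst_signal) {
  if (any(!is.finite(healthy_cst_signal)) || any(healthy_cst_signal <= 0))
    stopf("healthy CST signal must be positive")
  100 * lesioned_cst_signal / healthy_cst_signal
}

#' Neurite outgrowth score from grid intersections
#'
#' Counts intersections of neurites with the lines of a square grid and
#' divides by the number of cell bodies; each maximal run of neurite
#' pixels along a grid line is one intersection. When a control score is
#' given the score is normalized to it (PBS control = 1).
#'
#' @param neurite_mask logical matrix of neurite (skeleton) pixels.
#' @param grid_spacing_px grid line spacing in pixels (> 0).
#' @param n_cell_bodies number of cell bodies (> 0).
#' @param control_score optional score of the vehicle control.
#' @return list with `crossings`, `score` (crossings per cell body) and
#'   `normalized` (when a control is given).
#' @export
neurite_outgrowth_score <- function(neurite_mask, grid_spacing_px,
                                    n_cell_bodies, control_score = NULL) {
  if (n_cell_bodies <= 0) stopf("`n_cell_bodies` must be positive")
  if (grid_spacing_px <= 0) stopf("`grid_spacing_px` must be positive")
  m <- as.matrix(neurite_mask) > 0
  runs_of <- function(v) sum(rle(v)$values)
  cols <- seq(grid_spacing_px, ncol(m), by = grid_spacing_px)
  rows <- seq(grid_spacing_px, nrow(m), by = grid_spacing_px)
  crossings <- sum(vapply(cols, function(c) runs_of(m[, c]), numeric(1))) +
    sum(vapply(rows, function(r) runs_of(m[r, ]), numeric(1)))
  score <- crossings / n_cell_bodies
  out <- list(crossings = crossings, score = score)
  if (!is.null(control_score)) {
    if (control_score <= 0) stopf("`control_score` must be positive")
    out$normalized <- score / control_score
  }
  out
}
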