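## profile along a grid line averaged over `width_px` parallel sample
## lines offset perpendicular to it at 1-px spacing
sample_wide_profile <- function(image, p0, p1, type, width_px = 3) {
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * image$pixel_size_um
  perp <- if (type == "v") c(1, 0) else c(0, 1)
  prof <- NULL
  acc <- NULL
  for (o in offs) {
    pr <- sample_profile(image, p0 + o * perp, p1 + o * perp)
    if (is.null(acc)) { acc <- pr$values; prof <- pr }
    else acc <- acc + pr$values
  }
  prof$values <- acc / length(offs)
  prof
}

#' Count fiber crossings along the sampling grid of a registered section
#'
#' Samples a gray-value profile along each of the 40 grid lines (clipped to
#' the GM) at the image pixel pitch with bilinear interpolation, detects
#' fiber crossings as extended minima of depth `h`, and assembles per-line
#' counts into the 20 x 20 panel map: each crossing is added to the panel
#' owning the line edge it sits on (medial vertical edge, ventral horizontal
#' edge), so panel totals and line totals agree exactly.
#'
#' @param image a [section_image] registered into the template frame (from
#'   [warp_section()] or [gen_section()]).
#' @param grid a `sampling_grid` from [build_grid()].
#' @param h absolute extended-minima depth in gray levels; when `NULL`
#'   (default) the depth is `h_frac` of each profile's dynamic range, which
#'   makes counts invariant to affine intensity rescaling.
#' @param h_frac relative depth used when `h` is `NULL` (default 0.10).
#' @param polarity event polarity; defaults to the image polarity
#'   (DAB fibers are dark).
#' @param line_width_px profiles are averaged over this many parallel
#'   1-px-spaced sample lines centered on the grid line (default 3), the
#'   usual line-width setting of profile densitometry; averaging suppresses
#'   pixel noise without touching event depth.
#' @return list with `per_line` (named integer vector, v1..v20 then
#'   h1..h20), `raw_counts` (20 x 20 matrix, rows = ventral panel bands,
#'   cols = medial panel bands) and `events` (data.frame of detected
#'   crossings with line and panel assignments).
#' @export
quantify_section <- function(image, grid, h = NULL, h_frac = 0.1,
                             polarity = NULL, line_width_px = 3) {
  if (!inherits(image, "section_image")) stopf("`image` must be a section_image")
  if (image$frame != "template")
    stopf("image is not registered into the template frame")
  if (!inherits(grid, "sampling_grid")) stopf("`grid` must be a sampling_grid")
  polarity <- polarity %||% image$polarity
  gl <- grid_lines(grid)
  n <- grid$n
  per_line <- stats::setNames(
    integer(2L * n), c(paste0("v", seq_len(n)), paste0("h", seq_len(n))))
  events <- NULL
  for (i in seq_len(nrow(gl))) {
    li <- gl[i, ]
    if (is.na(li$from) || li$to - li$from < 2 * image$pixel_size_um) next
    p0 <- if (li$type == "v") c(li$at, li$from) else c(li$from, li$at)
    p1 <- if (li$type == "v") c(li$at, li$to) else c(li$to, li$at)
    prof <- sample_wide_profile(image, p0, p1, li$type, line_width_px)
    v <- prof$values
    if (anyNA(v)) stopf("grid line %s%d leaves the registered image",
                        li$type, li$index)
    hline <- h %||% (h_frac * (max(v) - min(v)))
    if (hline <= 0) next
    idx <- find_profile_minima(v, hline, polarity = polarity)
    if (!length(idx)) next
    pos <- li$from + prof$t_um[idx]
    per_line[line_label(li$type, li$index)] <- length(idx)
    events <- rbind(events, data.frame(
      line_type = li$type, line_index = li$index, pos_um = pos))
  }
  raw <- empty_panel_matrix(n)
  if (!is.null(events)) {
    pan <- assign_panel(grid, events$line_type, events$line_index,
                        events$pos_um)
    events$panel_row <- pan$panel_row
    events$panel_col <- pan$panel_col
    for (k in seq_len(nrow(pan)))
      raw[pan$panel_row[k], pan$panel_col[k]] <-
        raw[pan$panel_row[k], pan$panel_col[k]] + 1
  }
  list(per_line = per_line, raw_counts = raw, events = events)
}

#' Animal-specific normalization factor for fiber counts
#'
#' The tracing efficiency of each animal is normalized out by dividing its
#' fiber counts by the ratio of its mean labeled-CST gray value to the
#' cohort mean: `factor = mean(animal values) / cohort mean`.
#'
#' @param animal_cst_gray per-section mean gray values of the labeled
#'   dorsal CST area of one animal.
#' @param cohort_cst_gray cohort-wide mean CST gray value (scalar), or the
#'   vector of all animals' values (its mean is used).
#' @return positive scalar normalization factor.
#' @export
normalization_factor <- function(animal_cst_gray, cohort_cst_gray) {
  cohort <- mean(cohort_cst_gray)
  if (!is.finite(cohort) || cohort <= 0)
    stopf("cohort mean gray value must be positive")
  mean(animal_cst_gray) / cohort
}

#' Per-section fiber count map
#'
#' Bundles the raw 20 x 20 panel counts with the animal normalization
#' factor; `normalized_counts = raw_counts / norm_factor`.
#'
#' @param raw_counts 20 x 20 non-negative count matrix (or the result list
#'   of [quantify_section()]).
#' @param norm_factor positive scalar from [normalization_factor()].
#' @param meta named list (animal, level, section id).
#' @return object of class `fiber_count_map`.
#' @export
fiber_count_map <- function(raw_counts, norm_factor = 1, meta = list()) {
  if (is.list(raw_counts) && !is.null(raw_counts$raw_counts))
    raw_counts <- raw_counts$raw_counts
  if (any(raw_counts < 0)) stopf("raw counts must be non-negative")
  if (!is.finite(norm_factor) || norm_factor <= 0)
    stopf("`norm_factor` must be positive")
  structure(list(raw_counts = raw_counts, norm_factor = norm_factor,
                 normalized_counts = raw_counts / norm_factor,
                 meta = meta),
            class = "fiber_count_map")
}

#' @export
print.fiber_count_map <- function(x, ...) {
  cat(sprintf(
    "<fiber_count_map> %d x %d panels, %g raw crossings, factor %.4g\n",
    nrow(x$raw_counts), ncol(x$raw_counts), sum(x$raw_counts),
    x$norm_factor))
  invisible(x)
}

map_values <- function(map, which = c("normalized", "raw")) {
  which <- match.arg(which)
  if (inherits(map, "fiber_count_map"))
    return(if (which == "normalized") map$normalized_counts else map$raw_counts)
  as.matrix(map)
}

#' Sum panel counts over Rexed laminar groups
#'
#' Each panel's count is added to the laminar group containing its center;
#' panels whose centers fall outside the GM polygon are collected in an
#' `"extra-GM"` bucket, so the laminar sums always reproduce the map total
#' exactly.
#'
#' @param map a [fiber_count_map()] or plain matrix.
#' @param template a [gm_template].
#' @param grid the `sampling_grid` the map was built on (defaults to
#'   `build_grid(template)`).
#' @param which `"normalized"` (default) or `"raw"` counts.
#' @return named numeric vector of per-group sums (laminar groups in
#'   template order, then `"extra-GM"`).
#' @export
laminar_sums <- function(map, template, grid = NULL,
                         which = c("normalized", "raw")) {
  vals <- map_values(map, match.arg(which))
  grid <- grid %||% build_grid(template, n = nrow(vals))
  pc <- panel_centers(grid)
  lab <- classify_lamina(template, pc$x, pc$y)
  groups <- c(lamina_labels(template), "extra-GM")
  out <- stats::setNames(numeric(length(groups)), groups)
  v <- vals[cbind(pc$panel_row, pc$panel_col)]
  agg <- tapply(v, factor(lab, levels = groups), sum, default = 0)
  out[names(agg)] <- agg
  out
}

#' Count and bin midline-crossing fibers
#'
#' Detects fiber crossings along the midline axis profile (sampled at the
#' image pixel pitch), assigns each detected crossing to a `sample_step_um`
#' window along the dorsoventral axis, and sums consecutive windows into
#' `bin_width_um` bins.
#'
#' @inheritParams quantify_section
#' @param template a [gm_template] (defines the midline axis).
#' @param sample_step_um counting window along the midline (default 100).
#' @param bin_width_um reported bin width (default 200; must be a multiple
#'   of `sample_step_um`).
#' @return data.frame with `bin_start_um`, `bin_end_um`, `count`; attribute
#'   `window_counts` holds the per-window counts before binning.
#' @export
midline_crossings <- function(image, template, sample_step_um = 100,
                              bin_width_um = 200, h = NULL, h_frac = 0.1,
                              polarity = NULL, line_width_px = 3) {
  if (!inherits(image, "section_image")) stopf("`image` must be a section_image")
  if (image$frame != "template")
    stopf("image is not registered into the template frame")
  k <- bin_width_um / sample_step_um
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stopf("`bin_width_um` must be a positive multiple of `sample_step_um`")
  k <- as.integer(round(k))
  polarity <- polarity %||% image$polarity
  mid <- template$midline
  y0 <- min(mid[, 2]); y1 <- max(mid[, 2])
  prof <- sample_wide_profile(image, c(mid[1, 1], y0), c(mid[1, 1], y1),
                              "v", line_width_px)
  v <- prof$values
  if (anyNA(v)) stopf("midline axis leaves the registered image")
  hline <- h %||% (h_frac * (max(v) - min(v)))
  pos <- if (hline > 0)
    y0 + prof$t_um[find_profile_minima(v, hline, polarity = polarity)]
  else numeric(0)
  edges <- seq(y0, y1, by = sample_step_um)
  if (edges[length(edges)] < y1) edges <- c(edges, y1)
  wins <- if (length(pos))
    tabulate(findInterval(pos, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1L)
  else integer(length(edges) - 1L)
  bin_id <- (seq_along(wins) - 1L) %/% k
  counts <- as.integer(tapply(wins, bin_id, sum))
  starts <- edges[seq_along(counts) * k - k + 1L]
  ends <- pmin(starts + bin_width_um, y1)
  out <- data.frame(bin_start_um = starts, bin_end_um = ends,
                    count = counts)
  attr(out, "window_counts") <- wins
  attr(out, "window_edges") <- edges
  out
}

#' Group mean heat map and stroke-minus-sham difference map
#'
#' `group_heatmap` averages the normalized panel counts of a group of
#' sections elementwise; `difference_map` subtracts the sham mean map from
#' a group mean map (stroke minus sham).
#'
#' @param maps non-empty list of [fiber_count_map()] objects (or matrices)
#'   built on the same template grid.
#' @param which `"normalized"` (default) or `"raw"` counts.
#' @return 20 x 20 numeric matrix.
#' @export
group_heatmap <- function(maps, which = c("normalized", "raw")) {
  which <- match.arg(which)
  if (!is.list(maps) || length(maps) == 0L)
    stopf("`maps` must be a non-empty list of count maps")
  mats <- lapply(maps, map_values, which = which)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stopf("all maps must share the same panel dimensions")
  Reduce(`+`, mats) / length(mats)
}

#' @rdname group_heatmap
#' @param group,sham 20 x 20 mean maps from `group_heatmap`.
#' @export
difference_map <- function(group, sham) {
  group <- as.matrix(group); sham <- as.matrix(sham)
  if (!identical(dim(group), dim(sham)))
    stopf("maps must share the same panel dimensions")
  group - sham
}

#' Write per-line counts and panel maps as tidy CSV
#'
#' @param quant result of [quantify_section()].
#' @param path_lines,path_panels output CSV paths (either may be `NULL`).
#' @export
write_fiber_counts <- function(quant, path_lines = NULL,
                               path_panels = NULL) {
  if (!is.null(path_lines)) {
    pl <- data.frame(line = names(quant$per_line),
                     count = as.integer(quant$per_line))
    write.csv(pl, path_lines, row.names = FALSE)
  }
  if (!is.null(path_panels)) {
    m <- quant$raw_counts
    df <- data.frame(panel_row = rep(seq_len(nrow(m)), ncol(m)),
                     panel_col = rep(seq_len(ncol(m)), each = nrow(m)),
                     count = as.vector(m))
    write.csv(df, path_panels, row.names = FALSE)
  }
  invisible(NULL)
}
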