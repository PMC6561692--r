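#' Microglial activation index
#'
#' The ratio of the longest process of the cell to the diameter of its
#' soma. Activated microglia retract their processes and enlarge their
#' somata, so smaller values represent a more activated state.
#'
#' @param longest_process_um longest process length (um, >= 0), vectorized.
#' @param soma_diameter_um soma diameter (um, > 0), vectorized.
#' @return numeric vector of activation indices.
#' @examples
#' activation_index(30, 10)  # 3: ramified, resting
#' activation_index(5, 12)   # ~0.42: activated
#' @export
activation_index <- function(longest_process_um, soma_diameter_um) {
  if (any(!is.finite(soma_diameter_um)) || any(soma_diameter_um <= 0))
    stopf("`soma_diameter_um` must be positive")
  if (any(longest_process_um < 0))
    stopf("`longest_process_um` must be non-negative")
  longest_process_um / soma_diameter_um
}

#' Define the CST projection area as a staining-intensity level set
#'
#' The former corticospinal projection area (CPA) is outlined on a tracing
#' density image of healthy animals as the region holding at least `frac`
#' of the maximum staining intensity: the image is Gaussian-smoothed, the
#' level set at `frac * max` is thresholded, and the connected component
#' containing the maximum is returned. The alternative reading — smallest
#' region holding `frac` of the total signal mass — is available as
#' `method = "mass"`.
#'
#' @param density_image a [section_image] or numeric matrix of staining
#'   density (signal-bright).
#' @param frac intensity fraction in (0, 1), default 0.8.
#' @param smoothing_sigma_um Gaussian smoothing sigma (um, default 20).
#' @param pixel_size_um required when `density_image` is a plain matrix.
#' @param method `"levelset"` (default) or `"mass"`.
#' @return logical mask matrix of the CPA.
#' @export
define_cpa <- function(density_image, frac = 0.8, smoothing_sigma_um = 20,
                       pixel_size_um = NULL,
                       method = c("levelset", "mass")) {
  method <- match.arg(method)
  if (inherits(density_image, "section_image")) {
    mat <- density_image$data
    ps <- density_image$pixel_size_um
  } else {
    mat <- as.matrix(density_image)
    ps <- pixel_size_um %||% stopf("`pixel_size_um` required for matrix input")
  }
  if (!(frac > 0 && frac < 1)) stopf("`frac` must be in (0, 1)")
  if (diff(range(mat)) == 0)
    stopf("threshold error: density image is constant")
  sm <- if (smoothing_sigma_um > 0)
    EBImage::gblur(mat, sigma = smoothing_sigma_um / ps)
  else mat
  sm <- matrix(as.numeric(sm), nrow(mat), ncol(mat))
  peak <- which.max(sm)
  bin <- if (method == "levelset") {
    sm >= frac * max(sm)
  } else {
    # smallest region holding `frac` of total mass: highest-intensity
    # pixels down to the mass quantile
    ord <- order(sm, decreasing = TRUE)
    cum <- cumsum(sm[ord])
    k <- which(cum >= frac * sum(sm))[1]
    m <- matrix(FALSE, nrow(sm), ncol(sm))
    m[ord[seq_len(k)]] <- TRUE
    m
  }
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.numeric(lab), nrow(mat), ncol(mat))
  lab == lab[peak]
}

#' Semi-random even-coverage selection of marked cells
#'
#' Reimplements the 20-cell selection protocol: a square grid of random
#' spacing drawn from `spacing_range` (um) and random offset is laid over
#' the gray matter; each grid intersection inside the GM selects the
#' nearest not-yet-selected marked cell (ties broken by lowest cell index).
#' If fewer than `n_target` distinct cells result, the spacing shrinks by
#' 10% and selection restarts from scratch. If more result, `n_target` of
#' them are kept: by default a greedy farthest-point subset of the
#' selecting intersections (`keep = "spread"`, preserving the even spatial
#' coverage that motivates the grid), or the `n_target` smallest
#' intersection-to-cell distances (`keep = "nearest"`).
#'
#' @param cells data.frame with `x_um`, `y_um` (one row per marked cell;
#'   row order defines the tie-breaking index).
#' @param gm_mask logical GM mask matrix in the template frame (e.g.
#'   `region_masks(template)$GM`).
#' @param n_target number of cells to select (default 20).
#' @param spacing_range grid-spacing interval in um (default 50-100).
#' @param seed integer seed; selection is deterministic given the seed.
#' @param pixel_size_um,origin calibration of `gm_mask` (defaults taken
#'   from its `region_masks` attributes when present).
#' @param keep pruning rule when more than `n_target` cells are selected.
#' @param shrink spacing shrink factor per iteration (default 0.9).
#' @param max_iter iteration guard.
#' @return the selected rows of `cells` (exactly `n_target`), with
#'   `sel_distance_um` and the selecting intersection coordinates appended.
#' @export
semirandom_sample <- function(cells, gm_mask, n_target = 20,
                              spacing_range = c(50, 100), seed = 1,
                              pixel_size_um = NULL, origin = NULL,
                              keep = c("spread", "nearest"), shrink = 0.9,
                              max_iter = 60) {
  keep <- match.arg(keep)
  if (n_target < 1) stopf("`n_target` must be >= 1")
  if (is.list(gm_mask) && !is.null(gm_mask$GM)) {
    pixel_size_um <- pixel_size_um %||% attr(gm_mask, "pixel_size_um")
    origin <- origin %||% attr(gm_mask, "origin")
    gm_mask <- gm_mask$GM
  }
  ps <- pixel_size_um %||% stopf("`pixel_size_um` is required")
  origin <- origin %||% c(0, 0)
  in_gm <- mask_at(gm_mask, cells$x_um, cells$y_um, ps, origin)
  pool <- which(in_gm)
  if (length(pool) < n_target)
    stopf("insufficient cells: %d in GM, %d requested", length(pool),
          n_target)
  set.seed(as.integer(seed))
  xlim <- origin[1] + c(0, ncol(gm_mask)) * ps
  ylim <- origin[2] + c(0, nrow(gm_mask)) * ps
  s <- runif(1, spacing_range[1], spacing_range[2])
  for (iter in seq_len(max_iter)) {
    ox <- runif(1, 0, s); oy <- runif(1, 0, s)
    gx <- seq(xlim[1] + ox, xlim[2], by = s)
    gy <- seq(ylim[1] + oy, ylim[2], by = s)
    pts <- expand.grid(x = gx, y = gy)           # scan order: x fast, y slow
    keep_pt <- mask_at(gm_mask, pts$x, pts$y, ps, origin)
    pts <- pts[keep_pt, , drop = FALSE]
    sel <- integer(0); seld <- numeric(0)
    selx <- numeric(0); sely <- numeric(0)
    avail <- rep(TRUE, length(pool))
    for (i in seq_len(nrow(pts))) {
      if (!any(avail)) break
      d <- sqrt((cells$x_um[pool] - pts$x[i])^2 +
                (cells$y_um[pool] - pts$y[i])^2)
      d[!avail] <- Inf
      j <- which.min(d)                          # which.min: lowest index tie
      sel <- c(sel, pool[j]); seld <- c(seld, d[j])
      selx <- c(selx, pts$x[i]); sely <- c(sely, pts$y[i])
      avail[j] <- FALSE
    }
    if (length(sel) >= n_target) {
      pick <- if (length(sel) == n_target) {
        seq_len(n_target)
      } else if (keep == "nearest") {
        order(seld, sel)[seq_len(n_target)]
      } else {
        farthest_point_subset(selx, sely, n_target)
      }
      out <- cells[sel[pick], , drop = FALSE]
      out$sel_distance_um <- seld[pick]
      out$sel_x_um <- selx[pick]
      out$sel_y_um <- sely[pick]
      return(out)
    }
    s <- s * shrink
  }
  stopf("selection did not reach %d cells within %d spacing iterations",
        n_target, max_iter)
}

## greedy farthest-point thinning: keep k points maximizing spatial
## dispersion, seeded at the point closest to the centroid; deterministic
## (ties broken by scan order)
farthest_point_subset <- function(x, y, k) {
  n <- length(x)
  d0 <- (x - mean(x))^2 + (y - mean(y))^2
  kept <- which.min(d0)
  mind <- (x - x[kept])^2 + (y - y[kept])^2
  while (length(kept) < k) {
    nxt <- which.max(mind)
    kept <- c(kept, nxt)
    mind <- pmin(mind, (x - x[nxt])^2 + (y - y[nxt])^2)
  }
  kept
}

## region of template points under the priority rule
## CST > CPA > VH > DH > GM-other; points in none and outside GM -> "outside"
region_label <- function(x, y, masks) {
  ps <- attr(masks, "pixel_size_um")
  origin <- attr(masks, "origin")
  out <- rep("outside", length(x))
  gm <- mask_at(masks$GM, x, y, ps, origin)
  out[gm] <- "GM-other"
  for (nm in rev(c("CST", "CPA", "VH", "DH"))) {
    if (is.null(masks[[nm]])) next
    hit <- mask_at(masks[[nm]], x, y, ps, origin)
    out[hit] <- nm
  }
  out
}

#' Classify cells into regions of interest
#'
#' Labels each cell by the first matching region in priority order
#' CST > CPA > VH > DH > GM-other, computes the activation index, and drops
#' cells that lie outside every region and the GM (with a warning).
#'
#' @param cells data.frame with `x_um`, `y_um`, `soma_diameter_um`,
#'   `longest_process_um` (annotation input or
#'   [gen_microglia_field()] ground truth).
#' @param masks region mask list from [region_masks()] (include a CPA via
#'   its `cpa` argument to label the projection area).
#' @return data.frame of cell records with `region` and
#'   `activation_index`; excluded cells are reported in the
#'   `excluded` attribute.
#' @export
classify_regions <- function(cells, masks) {
  need <- c("x_um", "y_um", "soma_diameter_um", "longest_process_um")
  if (!all(need %in% names(cells)))
    stopf("`cells` must have columns %s", paste(need, collapse = ", "))
  cells$region <- region_label(cells$x_um, cells$y_um, masks)
  cells$activation_index <- activation_index(cells$longest_process_um,
                                             cells$soma_diameter_um)
  out <- cells[cells$region != "outside", , drop = FALSE]
  dropped <- cells[cells$region == "outside", , drop = FALSE]
  if (nrow(dropped))
    warning(sprintf("%d cell(s) outside all regions and the GM excluded",
                    nrow(dropped)), call. = FALSE)
  attr(out, "excluded") <- dropped
  out
}

panel_of_points <- function(grid, x, y) {
  n <- grid$n
  col <- clamp(floor((x - grid$x0) / grid$dx) + 1L, 1L, n)
  row <- clamp(floor((grid$y1 - y) / grid$dy) + 1L, 1L, n)
  inside <- x >= grid$x0 & x <= grid$x1 & y >= grid$y0 & y <= grid$y1
  data.frame(panel_row = row, panel_col = col, in_grid = inside)
}

#' Per-panel activation and density maps with fold changes versus sham
#'
#' Aggregates classified cell records onto the sampling grid: per-panel
#' mean activation index and cell count (density) for each group, plus
#' fold-change maps (group / sham). Panels with no sham cells have an
#' undefined fold change and are emitted as `NA` rather than infinite.
#'
#' @param records data.frame of cell records (see [classify_regions()])
#'   with a `group` column; cells outside the grid extent are ignored for
#'   the maps.
#' @param grid a `sampling_grid`.
#' @param sham label of the reference group (default `"sham"`).
#' @return list with per-group `activation` and `density` matrices and,
#'   when the sham group is present, `activation_fold` / `density_fold`
#'   maps for each non-sham group.
#' @export
activation_maps <- function(records, grid, sham = "sham") {
  if (!"group" %in% names(records)) stopf("`records` needs a `group` column")
  pan <- panel_of_points(grid, records$x_um, records$y_um)
  recs <- records[pan$in_grid, , drop = FALSE]
  pan <- pan[pan$in_grid, , drop = FALSE]
  n <- grid$n
  groups <- unique(as.character(recs$group))
  res <- list(activation = list(), density = list())
  for (g in groups) {
    i <- recs$group == g
    dens <- empty_panel_matrix(n)
    act <- empty_panel_matrix(n) * NA
    if (any(i)) {
      idx <- cbind(pan$panel_row[i], pan$panel_col[i])
      cnt <- tapply(rep(1, sum(i)), list(idx[, 1], idx[, 2]), sum)
      mean_ai <- tapply(recs$activation_index[i],
                        list(idx[, 1], idx[, 2]), mean)
      rows <- as.integer(rownames(cnt))
      cols <- as.integer(colnames(cnt))
      dens[rows, cols] <- ifelse(is.na(cnt), 0, cnt)
      act[rows, cols] <- mean_ai
    }
    res$density[[g]] <- dens
    res$activation[[g]] <- act
  }
  if (sham %in% groups) {
    res$activation_fold <- list(); res$density_fold <- list()
    sh_a <- res$activation[[sham]]; sh_d <- res$density[[sham]]
    for (g in setdiff(groups, sham)) {
      fa <- res$activation[[g]] / sh_a
      fa[is.na(sh_a)] <- NA
      fd <- res$density[[g]] / sh_d
      fd[sh_d == 0] <- NA
      res$activation_fold[[g]] <- fa
      res$density_fold[[g]] <- fd
    }
  }
  res
}

#' Read a microglia annotation table
#'
#' CSV with columns `section_id, cell_id, row, col, soma_diameter_um,
#' longest_process_um` (pixel positions, 0-based, top-left origin). Pixel
#' positions are converted to physical coordinates.
#'
#' @param path CSV path.
#' @param pixel_size_um pixel pitch of the annotated image.
#' @param origin physical (x, y) of its top-left corner.
#' @return data.frame with `x_um`, `y_um` appended.
#' @export
read_cell_annotations <- function(path, pixel_size_um, origin = c(0, 0)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "cell_id", "row", "col", "soma_diameter_um",
            "longest_process_um")
  if (!all(need %in% names(df)))
    stopf("cell CSV must have columns %s", paste(need, collapse = ", "))
  xy <- landmarks_px_to_um(df$row, df$col, pixel_size_um, origin)
  df$x_um <- xy[, 1]; df$y_um <- xy[, 2]
  df
}
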