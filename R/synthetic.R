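## Synthetic fixture generators: DAB-like fiber sections with exact
## grid-crossing ground truth, star-shaped microglia fields with planted
## activation indices, and negative-binomial count matrices with planted
## temporal expression patterns.

## densely resample a polyline (k x 2, um) at a fixed step; linear on the
## original segments, so line crossings of the resampled chain are the
## analytic crossings of the polyline
resample_polyline <- function(path, step_um) {
  seg <- sqrt(rowSums(diff(path)^2))
  keep <- seg > 0
  if (!any(keep)) return(path[1, , drop = FALSE])
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  t <- unique(c(seq(0, L, by = step_um), L))
  cbind(stats::approx(cl, path[, 1], xout = t)$y,
        stats::approx(cl, path[, 2], xout = t)$y)
}

## stamp dark strokes of half-width `radius_px` along dense px-coordinate
## samples into a logical mask
stamp_tube <- function(mask, rr, cc, radius_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- ceiling(radius_px) + 1L
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  m <- length(rr)
  R <- rep(round(rr), times = nrow(off)) + rep(off$dr, each = m)
  C <- rep(round(cc), times = nrow(off)) + rep(off$dc, each = m)
  d2 <- (R - rep(rr, times = nrow(off)))^2 + (C - rep(cc, times = nrow(off)))^2
  ok <- d2 <= radius_px^2 & R >= 1 & R <= nr & C >= 1 & C <= nc
  mask[cbind(R[ok], C[ok])] <- TRUE
  mask
}

## analytic transversal crossings of one polyline with one grid line.
## Returns a list with `events` (data.frame pos, sin_angle) or a character
## violation reason ("graze", "angle", "span-edge", "double").
polyline_line_events <- function(dense, type, at, span, prox_um,
                                 end_margin_um, buffer_um, min_sin,
                                 cluster_window_um = Inf) {
  d <- if (type == "v") dense[, 1] - at else dense[, 2] - at
  along <- if (type == "v") dense[, 2] else dense[, 1]
  near <- abs(d) < prox_um
  if (!any(near)) return(list(events = NULL))
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_pos <- numeric(0); ev_sin <- numeric(0)
  for (ci in which(r$values)) {
    a <- starts[ci]; b <- ends[ci]
    if (b == a) idx <- integer(0)
    else {
      dd <- d[a:b]
      idx <- which(dd[-length(dd)] * dd[-1] < 0 | dd[-length(dd)] == 0)
    }
    if (length(idx) == 0L) {
      # the fiber grazes the line without crossing: ambiguous dip
      return("graze")
    }
    if (length(idx) > 1L) return("double")
    i <- a + idx[1L] - 1L
    if (d[i] == d[i + 1L]) return("graze")      # tangent segment on line
    frac <- d[i] / (d[i] - d[i + 1L])
    pos <- along[i] + frac * (along[i + 1L] - along[i])
    # the fiber must leave the line's influence zone promptly: a tail
    # hovering near the line past its crossing blurs into extra minima
    if (max(abs(along[a:b] - pos)) > cluster_window_um) return("hover")
    step_len <- sqrt((d[i + 1L] - d[i])^2 + (along[i + 1L] - along[i])^2)
    sin_a <- abs(d[i + 1L] - d[i]) / step_len
    if (sin_a < min_sin) return("angle")
    lo <- span[1]; hi <- span[2]
    if (is.na(lo)) return("span-edge")
    if (pos >= lo + end_margin_um && pos <= hi - end_margin_um) {
      ev_pos <- c(ev_pos, pos); ev_sin <- c(ev_sin, sin_a)
    } else if (pos > lo - buffer_um && pos < hi + buffer_um) {
      return("span-edge")                        # too close to a span end
    }                                            # else: far outside, ignore
  }
  if (length(ev_pos))
    list(events = data.frame(pos = ev_pos, sin_angle = ev_sin))
  else list(events = NULL)
}

## random smooth fiber: correlated random walk, `n_seg` steps of `step_um`
random_fiber <- function(xlim, ylim, n_seg, step_um, turn_sd) {
  p0 <- c(runif(1, xlim[1], xlim[2]), runif(1, ylim[1], ylim[2]))
  th <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_seg, 0, turn_sd))
  cbind(p0[1] + cumsum(c(0, step_um * cos(th))),
        p0[2] + cumsum(c(0, step_um * sin(th))))
}

#' Generate a synthetic DAB-stained fiber section with exact ground truth
#'
#' Renders dark curvilinear fibers on a bright background in the template
#' coordinate frame and records, analytically from the fiber center-lines,
#' every transversal crossing with the template's 20 x 20 sampling grid and
#' with the midline axis. The generator only accepts fiber placements whose
#' crossings are unambiguous events for profile densitometry: crossings on
#' the same line are separated by at least `min_sep_px` pixels (never less
#' than 3 px), cross at an angle of at least `min_angle_deg` from the
#' line, keep clear of the clipped span ends, and fibers never graze a line
#' tangentially. Fibers violating a constraint are redrawn up to
#' `max_tries` times.
#'
#' @param template a [gm_template].
#' @param n_fibers number of fibers (>= 0).
#' @param contrast intensity drop of fiber strokes below background (> 0).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed; one pseudorandom stream per call, equal seeds
#'   give bit-identical output.
#' @param paths optional list of k x 2 matrices (um) of fiber center-lines;
#'   overrides random generation (placement constraints then warn instead
#'   of redrawing).
#' @param background background gray value.
#' @param width_px range the per-fiber stroke width (full width, px) is
#'   drawn from. Widths of at least 2 px keep every bilinear-interpolated
#'   dip at close to full contrast (see the methods vignette).
#' @param fiber_len_um approximate fiber length.
#' @param step_um,turn_sd correlated-random-walk step and turning noise.
#' @param min_sep_px minimum along-line separation of crossings (px).
#' @param min_angle_deg minimum crossing angle from the line (degrees).
#' @param max_tries redraw budget per fiber before a placement error.
#' @return list with `image` (a [section_image], template frame) and
#'   `truth` (class `section_truth`): `per_line` (named counts, v1..v20
#'   then h1..h20), `per_panel` (20 x 20 matrix, rows = ventral bands,
#'   cols = medial bands), `midline_positions_um`, `fiber_paths`, `events`.
#' @export
gen_section <- function(template, n_fibers = 40, contrast = 40,
                        noise_sd = 5, seed = 1, paths = NULL,
                        background = 200, width_px = c(2, 3),
                        fiber_len_um = 300, step_um = 15, turn_sd = 0.12,
                        min_sep_px = 8, min_angle_deg = 30,
                        max_tries = 250) {
  if (n_fibers < 0) stopf("`n_fibers` must be >= 0")
  if (contrast <= 0) stopf("`contrast` must be positive")
  grid <- tryCatch(build_grid(template),
                   error = function(e) stopf(
                     "template grid undefined: %s", conditionMessage(e)))
  set.seed(as.integer(seed))
  ps <- template$pixel_size_um
  sep_um <- min_sep_px * ps
  prox_um <- 4 * ps
  endm_um <- 4 * ps
  buffer_um <- 5 * ps
  min_sin <- sin(min_angle_deg * pi / 180)

  gl <- grid_lines(grid)
  mid_x <- template$midline[1, 1]
  lines_df <- rbind(gl, data.frame(
    type = "mid", index = 1L, at = mid_x,
    from = min(template$midline[, 2]), to = max(template$midline[, 2])))
  registry <- vector("list", nrow(lines_df))   # accepted positions per line
  for (i in seq_len(nrow(lines_df))) registry[[i]] <- numeric(0)

  eval_fiber <- function(path) {
    dense <- resample_polyline(path, 0.3 * ps)
    evs <- NULL
    for (i in seq_len(nrow(lines_df))) {
      li <- lines_df[i, ]
      ltype <- if (li$type == "mid") "v" else li$type
      res <- polyline_line_events(
        dense, ltype, li$at, c(li$from, li$to), prox_um, endm_um,
        buffer_um, min_sin, cluster_window_um = sep_um)
      if (is.character(res)) return(res)
      if (!is.null(res$events)) {
        pos <- res$events$pos
        all_pos <- c(registry[[i]], pos)
        if (length(all_pos) > 1L && min(diff(sort(all_pos))) < sep_um)
          return("separation")
        evs <- rbind(evs, data.frame(
          line_row = i, line_type = li$type, line_index = li$index,
          pos_um = pos, sin_angle = res$events$sin_angle))
      }
    }
    list(events = evs)
  }

  accepted_paths <- list()
  all_events <- NULL
  if (is.null(paths)) {
    bb <- gm_bbox(template)
    n_seg <- max(2L, round(fiber_len_um / step_um))
    for (f in seq_len(n_fibers)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_fiber(c(bb$xlim[1] - 100, bb$xlim[2]), bb$ylim,
                             n_seg, step_um, turn_sd)
        res <- eval_fiber(cand)
        if (is.character(res)) next
        accepted_paths[[f]] <- cand
        if (!is.null(res$events)) {
          res$events$fiber <- f
          for (i in unique(res$events$line_row))
            registry[[i]] <- c(registry[[i]],
                               res$events$pos_um[res$events$line_row == i])
          all_events <- rbind(all_events, res$events)
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("unable to place fiber %d within %d tries", f, max_tries)
    }
  } else {
    for (f in seq_along(paths)) {
      path <- as.matrix(paths[[f]])
      if (ncol(path) != 2L || nrow(path) < 2L)
        stopf("each fiber path must be a k x 2 matrix with k >= 2")
      res <- eval_fiber(path)
      if (is.character(res)) {
        warning(sprintf(
          "fiber %d violates the placement constraint '%s'; its ambiguous crossings are excluded from ground truth",
          f, res), call. = FALSE)
        accepted_paths[[f]] <- path
        next
      }
      accepted_paths[[f]] <- path
      if (!is.null(res$events)) {
        res$events$fiber <- f
        for (i in unique(res$events$line_row))
          registry[[i]] <- c(registry[[i]],
                             res$events$pos_um[res$events$line_row == i])
        all_events <- rbind(all_events, res$events)
      }
    }
  }

  # render
  d <- frame_dims(template)
  img <- matrix(background, d["nrow"], d["ncol"])
  origin <- c(template$frame_xlim[1], template$frame_ylim[1])
  if (length(accepted_paths)) {
    mask <- matrix(FALSE, d["nrow"], d["ncol"])
    for (path in accepted_paths) {
      w <- runif(1, width_px[1], width_px[2])
      dense <- resample_polyline(path, 0.3 * ps)
      rr <- (dense[, 2] - origin[2]) / ps + 0.5
      cc <- (dense[, 1] - origin[1]) / ps + 0.5
      mask <- stamp_tube(mask, rr, cc, w / 2)
    }
    img[mask] <- background - contrast
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))

  # assemble ground truth
  n <- grid$n
  per_line <- stats::setNames(
    integer(2L * n), c(paste0("v", seq_len(n)), paste0("h", seq_len(n))))
  per_panel <- empty_panel_matrix(n)
  midline_pos <- numeric(0)
  if (!is.null(all_events)) {
    gv <- all_events[all_events$line_type %in% c("v", "h"), , drop = FALSE]
    if (nrow(gv)) {
      lab <- line_label(gv$line_type, gv$line_index)
      tab <- table(lab)
      per_line[names(tab)] <- as.integer(tab)
      pan <- assign_panel(grid, gv$line_type, gv$line_index, gv$pos_um)
      for (k in seq_len(nrow(pan)))
        per_panel[pan$panel_row[k], pan$panel_col[k]] <-
          per_panel[pan$panel_row[k], pan$panel_col[k]] + 1
    }
    midline_pos <- sort(all_events$pos_um[all_events$line_type == "mid"])
  }
  truth <- structure(
    list(per_line = per_line, per_panel = per_panel,
         midline_positions_um = midline_pos,
         fiber_paths = accepted_paths,
         events = all_events,
         params = list(contrast = contrast, noise_sd = noise_sd,
                       background = background, seed = seed)),
    class = "section_truth")
  image <- section_image(img, ps, origin = origin, stain = "BDA-DAB",
                         polarity = "dark", frame = "template",
                         meta = list(seed = seed, synthetic = TRUE))
  list(image = image, truth = truth)
}

#' @export
print.section_truth <- function(x, ...) {
  cat(sprintf(
    "<section_truth> %d fibers, %d grid crossings, %d midline crossings\n",
    length(x$fiber_paths), sum(x$per_line), length(x$midline_positions_um)))
  invisible(x)
}

#' Generate a synthetic microglia field with planted activation indices
#'
#' Places non-overlapping star-shaped cells (disk soma plus radial
#' processes, DAB-dark on a bright background) inside the template GM and
#' records each cell's exact planted soma diameter, longest process length
#' and region label. The planted longest-process / soma-diameter ratio of
#' every cell lies in `index_range`.
#'
#' @param template a [gm_template].
#' @param n_cells number of cells (>= 0).
#' @param index_range interval the planted activation index is drawn from.
#' @param soma_range_um soma diameter range (um).
#' @param seed integer seed.
#' @param background,cell_contrast gray levels of background and cells.
#' @param max_tries placement attempts per cell before a placement error.
#' @return list with `image` (a [section_image]) and `cells` (data.frame
#'   `cell_id`, `x_um`, `y_um`, `soma_diameter_um`, `longest_process_um`,
#'   `activation_index`, `region`).
#' @export
gen_microglia_field <- function(template, n_cells = 30,
                                index_range = c(0.5, 4),
                                soma_range_um = c(8, 14), seed = 1,
                                background = 200, cell_contrast = 80,
                                max_tries = 200) {
  if (n_cells < 0) stopf("`n_cells` must be >= 0")
  if (any(index_range <= 0)) stopf("`index_range` must be positive")
  set.seed(as.integer(seed))
  ps <- template$pixel_size_um
  bb <- gm_bbox(template)
  soma <- runif(n_cells, soma_range_um[1], soma_range_um[2])
  index <- runif(n_cells, index_range[1], index_range[2])
  longest <- index * soma
  xs <- numeric(n_cells); ys <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, bb$xlim[1], bb$xlim[2])
      y <- runif(1, bb$ylim[1], bb$ylim[2])
      if (!point_in_gm(template, x, y)) next
      if (i > 1L) {
        j <- seq_len(i - 1L)
        if (any(sqrt((xs[j] - x)^2 + (ys[j] - y)^2) <
                (soma[j] + soma[i]) / 2 + 4)) next
      }
      xs[i] <- x; ys[i] <- y; placed <- TRUE; break
    }
    if (!placed)
      stopf("placement error: could not place cell %d without overlap", i)
  }

  d <- frame_dims(template)
  img <- matrix(background, d["nrow"], d["ncol"])
  origin <- c(template$frame_xlim[1], template$frame_ylim[1])
  mask <- matrix(FALSE, d["nrow"], d["ncol"])
  for (i in seq_len(n_cells)) {
    # soma disk
    th <- seq(0, 2 * pi, length.out = 40)
    for (rfrac in seq(0, 1, length.out = 6)) {
      rr <- (ys[i] + rfrac * soma[i] / 2 * sin(th) - origin[2]) / ps + 0.5
      cc <- (xs[i] + rfrac * soma[i] / 2 * cos(th) - origin[1]) / ps + 0.5
      mask <- stamp_tube(mask, rr, cc, 0.7)
    }
    # radial processes; the first carries the planted longest length
    n_proc <- sample(5:8, 1)
    ang <- runif(n_proc, 0, 2 * pi)
    lens <- c(longest[i], runif(n_proc - 1L, 0.25, 0.85) * longest[i])
    for (p in seq_len(n_proc)) {
      path <- rbind(c(xs[i], ys[i]),
                    c(xs[i] + lens[p] * cos(ang[p]),
                      ys[i] + lens[p] * sin(ang[p])))
      dense <- resample_polyline(path, 0.3 * ps)
      mask <- stamp_tube(mask, (dense[, 2] - origin[2]) / ps + 0.5,
                         (dense[, 1] - origin[1]) / ps + 0.5, 0.6)
    }
  }
  img[mask] <- background - cell_contrast
  image <- section_image(img, ps, origin = origin, stain = "Iba1-DAB",
                         polarity = "dark", frame = "template",
                         meta = list(seed = seed, synthetic = TRUE))
  masks <- region_masks(template)
  cells <- data.frame(
    cell_id = seq_len(n_cells), x_um = xs, y_um = ys,
    soma_diameter_um = soma, longest_process_um = longest,
    activation_index = index)
  cells$region <- if (n_cells) region_label(cells$x_um, cells$y_um, masks)
                  else character(0)
  list(image = image, cells = cells)
}

#' Design of a planted negative-binomial count matrix
#'
#' Describes a gene-by-sample count matrix over the experimental groups
#' (sham plus days post-injury) with disjoint planted gene sets following
#' the four temporal patterns: `"persistent-down"` (down at every
#' post-stroke point), `"late-up"` / `"late-down"` (shifted at 28 and 42
#' dpi only) and `"early-up"` (up at 4 and 7 dpi only).
#'
#' @param n_genes total gene count.
#' @param groups ordered group labels; must contain `"sham"`.
#' @param n_per_group samples per group.
#' @param baseline_mean expected counts of unperturbed genes.
#' @param dispersion NB dispersion phi (> 0), `Var = mu + phi mu^2`.
#' @param planted list of `list(pattern =, n =, lfc =)` entries; planted
#'   gene sets are assigned disjointly from the start of the gene list.
#' @return object of class `count_design`.
#' @export
plant_design <- function(n_genes = 5000,
                         groups = c("sham", "4", "7", "14", "28", "42"),
                         n_per_group = 5, baseline_mean = 200,
                         dispersion = 0.1,
                         planted = list(
                           list(pattern = "persistent-down", n = 50, lfc = 2),
                           list(pattern = "late-up", n = 50, lfc = 2),
                           list(pattern = "late-down", n = 50, lfc = 2),
                           list(pattern = "early-up", n = 50, lfc = 2))) {
  if (!"sham" %in% groups) stopf("`groups` must contain \"sham\"")
  if (dispersion <= 0) stopf("`dispersion` must be positive")
  pats <- c("persistent-down", "late-up", "late-down", "early-up")
  for (p in planted) {
    if (!p$pattern %in% pats)
      stopf("unknown pattern '%s'", p$pattern)
    if (!is.finite(p$lfc)) stopf("effect sizes must be finite")
  }
  if (sum(vapply(planted, `[[`, 0, "n")) > n_genes)
    stopf("more planted genes than `n_genes`")
  structure(list(n_genes = n_genes, groups = groups,
                 n_per_group = n_per_group, baseline_mean = baseline_mean,
                 dispersion = dispersion, planted = planted),
            class = "count_design")
}

pattern_multiplier <- function(pattern, groups, lfc) {
  mult <- rep(1, length(groups)); names(mult) <- groups
  post <- setdiff(groups, "sham")
  late <- intersect(c("28", "42"), groups)
  early <- intersect(c("4", "7"), groups)
  switch(pattern,
    "persistent-down" = mult[post] <- 2^(-lfc),
    "late-up" = mult[late] <- 2^lfc,
    "late-down" = mult[late] <- 2^(-lfc),
    "early-up" = mult[early] <- 2^lfc)
  mult
}

#' Simulate a count matrix with planted temporal patterns
#'
#' Draws gene-by-sample counts from a negative binomial
#' (`Var = mu + phi mu^2`) with group means shifted multiplicatively for
#' the planted gene sets of the design.
#'
#' @param design a [plant_design()] object.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix, genes x samples), `groups`
#'   (factor per sample) and `truth` (data.frame `gene`, `planted`,
#'   `pattern`, `lfc`).
#' @export
gen_counts <- function(design, seed = 1) {
  if (!inherits(design, "count_design")) design <- do.call(plant_design, design)
  set.seed(as.integer(seed))
  g <- design$n_genes
  groups <- rep(design$groups, each = design$n_per_group)
  ns <- length(groups)
  mu <- matrix(design$baseline_mean, g, ns)
  truth <- data.frame(gene = sprintf("gene_%04d", seq_len(g)),
                      planted = FALSE, pattern = NA_character_,
                      lfc = NA_real_, stringsAsFactors = FALSE)
  at <- 1L
  for (p in design$planted) {
    idx <- seq.int(at, length.out = p$n)
    at <- at + p$n
    mult <- pattern_multiplier(p$pattern, design$groups, p$lfc)
    mu[idx, ] <- design$baseline_mean *
      matrix(mult[groups], length(idx), ns, byrow = TRUE)
    truth$planted[idx] <- TRUE
    truth$pattern[idx] <- p$pattern
    truth$lfc[idx] <- p$lfc
  }
  counts <- matrix(rnbinom(g * ns, mu = mu, size = 1 / design$dispersion),
                   g, ns)
  dimnames(counts) <- list(truth$gene,
                           paste(groups, sequence(rle(groups)$lengths),
                                 sep = "_"))
  list(counts = counts,
       groups = factor(groups, levels = design$groups), truth = truth)
}
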