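#' Gray-matter template of a spinal hemicord
#'
#' A `gm_template` holds the predefined geometry every section is registered
#' into: the gray-matter (GM) outline, the midline axis, the ventral GM-WM
#' border, a partition of the GM into Rexed laminar groups, five anchor
#' landmarks, and white-matter regions of interest (dorsal-funiculus CST).
#' Physical coordinates are micrometers: x medial to lateral with the midline
#' at the template's medial edge, y dorsal to ventral (downwards).
#'
#' @param gm_polygon k x 2 matrix (x, y) of the GM outline. Stored closed.
#' @param midline 2 x 2 matrix, dorsal and ventral endpoints of the midline
#'   axis.
#' @param ventral_border m x 2 matrix polyline of the ventral GM-WM border.
#' @param laminae list with `bands` (data.frame `label`, `ymin`, `ymax`
#'   covering the GM dorsoventral extent, dorsal first) and optional `strip`
#'   (list `label`, `xmax`, `ymin`, `ymax`) for the medial lamina X field,
#'   which overrides the band label.
#' @param anchors 5 x 2 matrix of landmark anchor coordinates.
#' @param regions named list of axis-aligned rectangles
#'   (`c(xmin, xmax, ymin, ymax)`) for `CST`, `VH`, `DH`.
#' @param pixel_size_um raster pitch used when the template frame is
#'   rasterized.
#' @param frame_xlim,frame_ylim physical extent of the raster frame; must
#'   contain the GM polygon and the regions.
#' @return object of class `gm_template`.
#' @seealso [hemicord_template()] for the packaged cervical hemicord
#'   template, [build_grid()] for the sampling grid derived from it.
#' @export
gm_template <- function(gm_polygon, midline, ventral_border, laminae,
                        anchors, regions = list(), pixel_size_um = 5,
                        frame_xlim = NULL, frame_ylim = NULL) {
  gm_polygon <- as.matrix(gm_polygon)
  if (ncol(gm_polygon) != 2L || nrow(gm_polygon) < 3L)
    stopf("`gm_polygon` must be a k x 2 matrix with k >= 3")
  # store closed (first vertex repeated) for point-in-polygon tests
  if (any(gm_polygon[1, ] != gm_polygon[nrow(gm_polygon), ]))
    gm_polygon <- rbind(gm_polygon, gm_polygon[1, ])
  anchors <- as.matrix(anchors)
  if (!identical(dim(anchors), c(5L, 2L)))
    stopf("`anchors` must be a 5 x 2 matrix (five defined landmarks)")
  if (anyDuplicated(anchors)) stopf("anchor landmarks must be distinct")
  frame_xlim <- frame_xlim %||% (range(gm_polygon[, 1]) + c(-200, 200))
  frame_ylim <- frame_ylim %||% (range(gm_polygon[, 2]) + c(-300, 300))
  tpl <- structure(
    list(gm_polygon = gm_polygon, midline = as.matrix(midline),
         ventral_border = as.matrix(ventral_border), laminae = laminae,
         anchors = anchors, regions = regions,
         pixel_size_um = pixel_size_um,
         frame_xlim = as.numeric(frame_xlim),
         frame_ylim = as.numeric(frame_ylim)),
    class = "gm_template")
  mid_ok <- any(point_in_gm(tpl, tpl$midline[, 1], tpl$midline[, 2])) ||
    min(abs(tpl$midline[1, 1] - range(gm_polygon[, 1]))) < 1e-6
  if (!mid_ok) stopf("midline axis does not touch the GM polygon")
  tpl
}

#' @export
print.gm_template <- function(x, ...) {
  bb <- gm_bbox(x)
  cat(sprintf(
    "<gm_template> GM %g x %g um, frame x [%g, %g] y [%g, %g], %g um/px\n",
    diff(bb$xlim), diff(bb$ylim), x$frame_xlim[1], x$frame_xlim[2],
    x$frame_ylim[1], x$frame_ylim[2], x$pixel_size_um))
  cat(sprintf("  laminar groups: %s\n",
              paste(lamina_labels(x), collapse = ", ")))
  invisible(x)
}

gm_bbox <- function(template) {
  list(xlim = range(template$gm_polygon[, 1]),
       ylim = range(template$gm_polygon[, 2]))
}

frame_dims <- function(template) {
  c(nrow = ceiling(diff(template$frame_ylim) / template$pixel_size_um),
    ncol = ceiling(diff(template$frame_xlim) / template$pixel_size_um))
}

lamina_labels <- function(template) {
  c(template$laminae$bands$label,
    if (!is.null(template$laminae$strip)) template$laminae$strip$label)
}

#' Point-in-GM test
#'
#' @param template a [gm_template].
#' @param x,y physical coordinates (um), vectorized.
#' @return logical vector.
#' @export
point_in_gm <- function(template, x, y) {
  mgcv::in.out(template$gm_polygon, cbind(as.numeric(x), as.numeric(y)))
}

#' Laminar group of template points
#'
#' Each GM point belongs to exactly one laminar group: the medial lamina X
#' strip when defined and containing the point, otherwise the dorsoventral
#' band holding its y coordinate. Points outside the GM polygon are labeled
#' `"extra-GM"`.
#'
#' @inheritParams point_in_gm
#' @return character vector of laminar labels.
#' @export
classify_lamina <- function(template, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  out <- rep("extra-GM", length(x))
  inside <- point_in_gm(template, x, y)
  bands <- template$laminae$bands
  for (i in seq_len(nrow(bands))) {
    sel <- inside & y >= bands$ymin[i] & y < bands$ymax[i]
    out[sel] <- bands$label[i]
  }
  # close the ventral-most band at its lower edge
  last <- nrow(bands)
  out[inside & y == bands$ymax[last]] <- bands$label[last]
  st <- template$laminae$strip
  if (!is.null(st)) {
    sel <- inside & x <= st$xmax & y >= st$ymin & y <= st$ymax
    out[sel] <- st$label
  }
  out
}

#' Packaged cervical hemicord GM template
#'
#' A simplified convex outline of one hemicord's gray matter at cervical
#' level (about 1.2 mm mediolateral by 1.6 mm dorsoventral), with the
#' midline at x = 0, laminar groups I-III / IV-V / VI-VII / VIII-IX split
#' dorsoventrally (30/20/20/30% of the GM height) plus a medial lamina X
#' strip around the central canal, five anchor landmarks on the outline, and
#' a dorsal-funiculus CST rectangle in the white matter dorsomedial to the
#' GM. Ventral horn (VH) and dorsal horn (DH) regions reuse the outer
#' laminar bands.
#'
#' @param pixel_size_um raster pitch of the template frame (default 5).
#' @return a [gm_template].
#' @export
hemicord_template <- function(pixel_size_um = 5) {
  pts <- rbind(
    c(0, 100), c(250, 0), c(550, 60), c(850, 300), c(1100, 700),
    c(1200, 1050), c(1100, 1380), c(800, 1560), c(450, 1600),
    c(120, 1560), c(0, 1400))
  pts <- pts[rev(grDevices::chull(pts)), , drop = FALSE]  # convex, cw order
  laminae <- list(
    bands = data.frame(
      label = c("I-III", "IV-V", "VI-VII", "VIII-IX"),
      ymin = c(0, 480, 800, 1120),
      ymax = c(480, 800, 1120, 1600)),
    strip = list(label = "X", xmax = 150, ymin = 720, ymax = 1040))
  gm_template(
    gm_polygon = pts,
    midline = rbind(c(0, 0), c(0, 1600)),
    ventral_border = rbind(c(0, 1400), c(120, 1560), c(450, 1600),
                           c(800, 1560)),
    laminae = laminae,
    anchors = rbind(c(0, 100), c(550, 60), c(1200, 1050), c(450, 1600),
                    c(0, 1400)),
    regions = list(
      CST = c(xmin = 0, xmax = 350, ymin = -250, ymax = -50),
      VH = c(xmin = 0, xmax = 1200, ymin = 1120, ymax = 1600),
      DH = c(xmin = 0, xmax = 1200, ymin = 0, ymax = 480)),
    pixel_size_um = pixel_size_um,
    frame_xlim = c(-200, 1400), frame_ylim = c(-300, 1900))
}

#' Rectangular toy template
#'
#' A rectangular GM of the given size, used in unit tests and examples where
#' exact grid spacing and 50/50 laminar splits are needed.
#'
#' @param width_um,height_um rectangle size.
#' @param pixel_size_um raster pitch.
#' @return a [gm_template].
#' @export
toy_rect_template <- function(width_um = 2000, height_um = 2000,
                              pixel_size_um = 5) {
  pts <- rbind(c(0, 0), c(width_um, 0), c(width_um, height_um),
               c(0, height_um))
  gm_template(
    gm_polygon = pts,
    midline = rbind(c(0, 0), c(0, height_um)),
    ventral_border = rbind(c(0, height_um), c(width_um, height_um)),
    laminae = list(bands = data.frame(
      label = c("dorsal-half", "ventral-half"),
      ymin = c(0, height_um / 2), ymax = c(height_um / 2, height_um))),
    anchors = rbind(c(0, 0), c(width_um, 0), c(width_um, height_um),
                    c(0, height_um), c(width_um / 2, height_um / 2)),
    pixel_size_um = pixel_size_um,
    frame_xlim = c(-100, width_um + 100),
    frame_ylim = c(-100, height_um + 100))
}

in_rect <- function(r, x, y) {
  x >= r["xmin"] & x <= r["xmax"] & y >= r["ymin"] & y <= r["ymax"]
}

#' Rasterized region masks in the template frame
#'
#' Returns logical matrices (template raster frame) for the GM and the
#' regions of interest used by the microglia module: ventral horn (`VH`),
#' dorsal horn (`DH`), the dorsal-funiculus `CST` (white matter, disjoint
#' from the GM by construction), and optionally a corticospinal projection
#' area (`CPA`) mask computed by [define_cpa()]. VH and DH are restricted to
#' the GM; the CPA is intersected with the GM, honoring its invariant
#' CPA within GM.
#'
#' @param template a [gm_template].
#' @param cpa optional logical matrix of the CPA in the same frame.
#' @return named list of logical matrices plus `pixel_size_um` / `origin`
#'   attributes.
#' @export
region_masks <- function(template, cpa = NULL) {
  d <- frame_dims(template)
  ps <- template$pixel_size_um
  cx <- template$frame_xlim[1] + (seq_len(d["ncol"]) - 0.5) * ps
  cy <- template$frame_ylim[1] + (seq_len(d["nrow"]) - 0.5) * ps
  x <- rep(cx, each = d["nrow"])
  y <- rep(cy, times = d["ncol"])
  gm <- matrix(point_in_gm(template, x, y), d["nrow"], d["ncol"])
  masks <- list(GM = gm)
  for (nm in names(template$regions)) {
    m <- matrix(in_rect(template$regions[[nm]], x, y), d["nrow"], d["ncol"])
    if (nm %in% c("VH", "DH")) m <- m & gm
    if (nm == "CST") m <- m & !gm
    masks[[nm]] <- m
  }
  if (!is.null(cpa)) {
    if (!identical(dim(cpa), unname(dim(gm))) &&
        !identical(dim(cpa), dim(gm)))
      stopf("`cpa` mask dimensions do not match the template frame")
    masks$CPA <- cpa & gm
  }
  attr(masks, "pixel_size_um") <- ps
  attr(masks, "origin") <- c(template$frame_xlim[1], template$frame_ylim[1])
  masks
}

mask_at <- function(mask, x, y, pixel_size_um, origin) {
  r <- round((y - origin[2]) / pixel_size_um + 0.5)
  c <- round((x - origin[1]) / pixel_size_um + 0.5)
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  out <- rep(FALSE, length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  out
}

#' Write / read a template as a YAML bundle
#'
#' Serializes the template geometry (polygons, laminae, anchors, regions,
#' frame) to a plain-text YAML file.
#'
#' @param template a [gm_template].
#' @param path file path.
#' @return `template_from_yaml` returns a [gm_template].
#' @export
template_to_yaml <- function(template, path) {
  obj <- list(
    gm_polygon = unname(apply(template$gm_polygon, 1, as.list)),
    midline = unname(apply(template$midline, 1, as.list)),
    ventral_border = unname(apply(template$ventral_border, 1, as.list)),
    laminae = list(
      bands = lapply(seq_len(nrow(template$laminae$bands)), function(i)
        as.list(template$laminae$bands[i, ])),
      strip = template$laminae$strip),
    anchors = unname(apply(template$anchors, 1, as.list)),
    regions = lapply(template$regions, as.list),
    pixel_size_um = template$pixel_size_um,
    frame_xlim = template$frame_xlim, frame_ylim = template$frame_ylim)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname template_to_yaml
#' @export
template_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  as_mat <- function(l) do.call(rbind, lapply(l, unlist))
  bands <- do.call(rbind, lapply(obj$laminae$bands, as.data.frame))
  gm_template(
    gm_polygon = as_mat(obj$gm_polygon),
    midline = as_mat(obj$midline),
    ventral_border = as_mat(obj$ventral_border),
    laminae = list(bands = bands, strip = obj$laminae$strip),
    anchors = as_mat(obj$anchors),
    regions = lapply(obj$regions, unlist),
    pixel_size_um = obj$pixel_size_um,
    frame_xlim = unlist(obj$frame_xlim),
    frame_ylim = unlist(obj$frame_ylim))
}
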