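# Spatial scaffolding: cell/nucleus ROIs, compartment masks, sampling lines
# and front sectors.
#
# Conventions (used throughout the package):
#  * continuous coordinates are 0-based, (x, y) = (column, row);
#  * an image matrix `img[r, c]` covers x in [c-1, c), y in [r-1, r);
#    the pixel center is (c - 0.5, r - 0.5);
#  * a pixel belongs to a rasterized region iff its center is inside the
#    polygon (half-open rasterization).

#' Cell region of interest
#'
#' Bundle a cell outline and a nucleus outline (closed polygons in pixel
#' coordinates) into a validated ROI.  The nucleus centroid is computed from
#' the nucleus polygon.
#'
#' @param cell_outline numeric matrix (or data.frame) with columns `x`, `y`;
#'   vertices of a simple closed polygon.  The closing vertex may be
#'   repeated or omitted.
#' @param nucleus_outline nucleus polygon, same format; must lie inside the
#'   cell outline.
#' @param pixel_size physical pixel size in micrometres per pixel (default 1).
#' @return An object of class `cell_roi` with elements `cell_outline`,
#'   `nucleus_outline`, `nucleus_centroid` (length-2 `(x, y)`) and
#'   `pixel_size`.
#' @examples
#' roi <- cell_roi(circle_polygon(100, c(120, 120)),
#'                 circle_polygon(30, c(120, 120)))
#' roi$nucleus_centroid
#' @export
cell_roi <- function(cell_outline, nucleus_outline, pixel_size = 1) {
  cell <- as_polygon(cell_outline)
  nuc  <- as_polygon(nucleus_outline)
  if (abs(polygon_area(cell)) < 10)
    trk_stop("degenerate-roi", "cell outline area below 10 px^2")
  if (abs(polygon_area(nuc)) < 1)
    trk_stop("degenerate-roi", "nucleus outline is degenerate")
  if (!all(points_in_polygon(nuc, cell)))
    trk_stop("invalid-roi", "nucleus outline must lie inside the cell outline")
  ctr <- polygon_centroid(nuc)
  if (!points_in_polygon(rbind(ctr), nuc))
    trk_stop("invalid-roi", "nucleus centroid falls outside the nucleus outline")
  structure(list(cell_outline = cell, nucleus_outline = nuc,
                 nucleus_centroid = ctr, pixel_size = pixel_size),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf(
    "<cell_roi> cell area %.0f px^2, nucleus area %.0f px^2, centroid (%.1f, %.1f), %g um/px\n",
    abs(polygon_area(x$cell_outline)), abs(polygon_area(x$nucleus_outline)),
    x$nucleus_centroid[1], x$nucleus_centroid[2], x$pixel_size))
  invisible(x)
}

#' Regular polygon approximating a circle (or ellipse)
#'
#' Convenience constructor used by examples, tests and the scene simulator.
#'
#' @param radius circle radius in pixels; for an ellipse give `axis_ratio`.
#' @param center length-2 `(x, y)` center.
#' @param n number of vertices.
#' @param axis_ratio major/minor axis ratio (1 = circle).
#' @param phase rotation of the major axis (radians).
#' @return vertex matrix with columns `x`, `y`.
#' @export
circle_polygon <- function(radius, center = c(0, 0), n = 72,
                           axis_ratio = 1, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- radius * sqrt(axis_ratio)
  b <- radius / sqrt(axis_ratio)
  x <- a * cos(th)
  y <- b * sin(th)
  cbind(x = center[1] + x * cos(phase) - y * sin(phase),
        y = center[2] + x * sin(phase) + y * cos(phase))
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) < 2 || nrow(p) < 3) trk_stop("degenerate-roi", "polygon needs >= 3 vertices")
  p <- p[, 1:2, drop = FALSE]
  colnames(p) <- c("x", "y")
  storage.mode(p) <- "double"
  # drop an explicit closing vertex
  if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(x = sum((x + x[j]) * cr) / (6 * a), y = sum((y + y[j]) * cr) / (6 * a))
}

# pts: n x 2 matrix of (x, y); returns logical vector
points_in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(bnd, as.matrix(pts))
}

# rasterize a polygon onto a height x width grid (pixel-center rule)
rasterize_polygon <- function(poly, width, height) {
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  pts <- cbind(rep(xs, each = height), rep(ys, times = width))
  matrix(points_in_polygon(pts, poly), nrow = height, ncol = width)
}

# default raster frame for an ROI: tight bounding box plus margin
roi_frame <- function(roi, margin = 2L) {
  w <- as.integer(ceiling(max(roi$cell_outline[, 1]))) + margin
  h <- as.integer(ceiling(max(roi$cell_outline[, 2]))) + margin
  if (min(roi$cell_outline) < 0)
    trk_stop("invalid-roi", "outline has negative coordinates; shift the ROI first")
  c(width = w, height = h)
}

#' Perinuclear and peripheral compartment masks
#'
#' Rasterizes a cell ROI into three boolean masks: the whole cell, a
#' perinuclear band hugging the nucleus and a peripheral band hugging the
#' plasma membrane.  Band widths are expressed as fractions of `R`, the mean
#' distance from the nucleus boundary to the cell boundary, so the same
#' settings adapt to cells of different sizes.
#'
#' The perinuclear mask contains pixels outside the nucleus whose distance
#' to the nucleus boundary is at most `perinuclear_band * R`; the peripheral
#' mask contains pixels whose distance to the cell boundary is at most
#' `peripheral_band * R`.  Where the two bands would meet (e.g. a nucleus
#' touching the cell edge) the peripheral band takes precedence, so the
#' masks are disjoint by construction.
#'
#' @param roi a [cell_roi()].
#' @param perinuclear_band,peripheral_band band widths as fractions of the
#'   mean nucleus-to-membrane distance; their sum must be < 1.
#' @param dim optional raster size as `c(width, height)`; defaults to the
#'   ROI bounding box.
#' @return An object of class `compartment_masks`: logical matrices
#'   `perinuclear`, `peripheral`, `cell`, `nucleus`, plus `band_params` and
#'   the scale `R` (pixels).
#' @examples
#' roi <- cell_roi(circle_polygon(100, c(110, 110)), circle_polygon(30, c(110, 110)))
#' m <- build_compartment_masks(roi)
#' sum(m$perinuclear & m$peripheral)  # always 0
#' @export
build_compartment_masks <- function(roi, perinuclear_band = 0.25,
                                    peripheral_band = 0.15, dim = NULL) {
  stopifnot(inherits(roi, "cell_roi"))
  if (perinuclear_band <= 0 || peripheral_band <= 0)
    trk_stop("bad-config", "band fractions must be positive")
  if (perinuclear_band + peripheral_band >= 1)
    trk_stop("bands-overlap",
             sprintf("perinuclear_band + peripheral_band = %.2f >= 1",
                     perinuclear_band + peripheral_band))
  if (abs(polygon_area(roi$cell_outline)) < 10)
    trk_stop("degenerate-roi", "cell area below 10 px^2")

  fr <- if (is.null(dim)) roi_frame(roi) else c(width = dim[1], height = dim[2])
  cell <- rasterize_polygon(roi$cell_outline, fr["width"], fr["height"])
  nuc  <- rasterize_polygon(roi$nucleus_outline, fr["width"], fr["height"])
  nuc  <- nuc & cell

  # distance transforms (pixel units): to cell background and to nucleus
  d_edge <- as.matrix(EBImage::distmap(matrix(as.numeric(cell), nrow(cell))))
  d_nuc  <- as.matrix(EBImage::distmap(matrix(as.numeric(!nuc), nrow(nuc))))

  # nucleus boundary pixels: in nucleus, 4-neighbour outside
  nb <- nuc & !(shift_mask(nuc, 1, 0) & shift_mask(nuc, -1, 0) &
                shift_mask(nuc, 0, 1) & shift_mask(nuc, 0, -1))
  if (!any(nb)) trk_stop("degenerate-roi", "nucleus rasterizes to nothing")
  R <- mean(d_edge[nb] - 0.5)
  if (R <= 0) trk_stop("degenerate-roi", "nucleus reaches the cell boundary everywhere")

  peripheral  <- cell & (d_edge - 0.5 <= peripheral_band * R)
  perinuclear <- cell & !nuc & (d_nuc - 0.5 <= perinuclear_band * R) & !peripheral

  structure(list(perinuclear = perinuclear, peripheral = peripheral,
                 cell = cell, nucleus = nuc,
                 band_params = c(perinuclear_band = perinuclear_band,
                                 peripheral_band = peripheral_band),
                 R = R),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks> %d x %d px; cell %d, perinuclear %d, peripheral %d px; R = %.1f px\n",
              ncol(x$cell), nrow(x$cell), sum(x$cell), sum(x$perinuclear),
              sum(x$peripheral), x$R))
  invisible(x)
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rdst <- rs + dr; cdst <- cs + dc
  keep_r <- rdst >= 1 & rdst <= nrow(m)
  keep_c <- cdst >= 1 & cdst <= ncol(m)
  out[rdst[keep_r], cdst[keep_c]] <- m[rs[keep_r], cs[keep_c]]
  out
}

#' Radial sampling lines from the plasma membrane toward the nucleus
#'
#' Places line segments that start on the cell boundary and point toward the
#' nucleus centroid, the geometry underlying linescan intensity profiles.
#' By default segments are evenly spaced in angle starting at 0 (the +x
#' direction, angles measured at the nucleus centroid).
#'
#' @param roi a [cell_roi()].
#' @param n_lines number of lines (default 3, matching per-cell averaging of
#'   three linescans).
#' @param length nominal segment length in pixels; `NULL` (default) extends
#'   each segment all the way to the centroid.  Segments longer than the
#'   boundary-to-centroid distance are truncated at the centroid and
#'   flagged.
#' @param width slab width in pixels over which intensities are averaged
#'   perpendicular to the line (>= 1).
#' @param angles optional numeric vector of angles (radians) overriding the
#'   even default placement; its length overrides `n_lines`.
#' @return list of `sampling_segment` objects, each with `start`, `end`
#'   (length-2 `(x, y)`), `length`, `width`, `angle` and `truncated`.
#' @export
radial_lines <- function(roi, n_lines = 3, length = NULL, width = 3,
                         angles = NULL) {
  stopifnot(inherits(roi, "cell_roi"))
  if (is.null(angles)) {
    if (n_lines < 1) trk_stop("bad-config", "n_lines must be >= 1")
    angles <- seq(0, 2 * pi, length.out = n_lines + 1L)[seq_len(n_lines)]
  }
  if (!is.null(length) && length < 1) trk_stop("bad-config", "length must be >= 1")
  if (width < 1) trk_stop("bad-config", "width must be >= 1")
  ctr <- roi$nucleus_centroid
  lapply(angles, function(a) {
    u <- c(cos(a), sin(a))
    t_hit <- ray_polygon_hit(ctr, u, roi$cell_outline)
    start <- ctr + t_hit * u
    L <- if (is.null(length)) t_hit else length
    truncated <- L > t_hit
    if (truncated) L <- t_hit
    structure(list(start = start, end = start - L * u, length = L,
                   width = width, angle = a, truncated = truncated),
              class = "sampling_segment")
  })
}

# outermost intersection parameter t > 0 of ray origin + t*u with polygon
ray_polygon_hit <- function(origin, u, poly) {
  p1 <- poly
  p2 <- poly[c(seq_len(nrow(poly))[-1], 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  # solve origin + t*u = p1 + s*e,  0 <= s <= 1, t > 0
  den <- u[1] * ey - u[2] * ex
  ok <- abs(den) > 1e-12
  wx <- p1[, 1] - origin[1]; wy <- p1[, 2] - origin[2]
  t <- (wx * ey - wy * ex) / den
  s <- (wx * u[2] - wy * u[1]) / den
  hit <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(hit)) trk_stop("invalid-roi", "ray from centroid never crosses the outline")
  max(t[hit])
}

#' Front sector of a migrating cell
#'
#' Defines the angular sector with apex at the nucleus centroid that spans
#' the cell's migratory front, either from an explicit direction plus
#' angular half-width or from two points on the leading edge (the sector is
#' the minor arc between them).
#'
#' @param roi a [cell_roi()].
#' @param direction polar angle (radians) of the front direction.
#' @param half_width angular half-width in radians (sector spans
#'   `direction +/- half_width`).
#' @param edge_points 2 x 2 matrix of two `(x, y)` points on the cell front;
#'   alternative to `direction`/`half_width`.
#' @return `sector_region` object with `apex`, `direction`, `half_width`.
#' @export
front_sector <- function(roi, direction = NULL, half_width = NULL,
                         edge_points = NULL) {
  stopifnot(inherits(roi, "cell_roi"))
  apex <- unname(roi$nucleus_centroid)
  if (!is.null(edge_points)) {
    ep <- as.matrix(edge_points)
    if (nrow(ep) != 2) trk_stop("degenerate-sector", "need exactly two edge points")
    a1 <- atan2(ep[1, 2] - apex[2], ep[1, 1] - apex[1])
    a2 <- atan2(ep[2, 2] - apex[2], ep[2, 1] - apex[1])
    d <- angle_diff(a2, a1)
    if (abs(d) < 1e-9 && all(abs(ep[1, ] - ep[2, ]) < 1e-9))
      trk_stop("degenerate-sector", "edge points coincide")
    if (abs(d) < 1e-9) trk_stop("degenerate-sector", "edge points are collinear with the apex")
    direction <- a1 + d / 2
    half_width <- abs(d) / 2
  }
  if (is.null(direction) || is.null(half_width))
    trk_stop("degenerate-sector", "give direction + half_width or edge_points")
  if (half_width <= 0 || half_width >= pi)
    trk_stop("degenerate-sector", "angular width must lie in (0, 2*pi)")
  structure(list(apex = apex, direction = wrap_angle(direction),
                 half_width = half_width),
            class = "sector_region")
}

wrap_angle <- function(a) atan2(sin(a), cos(a))
# signed difference a - b wrapped to (-pi, pi]
angle_diff <- function(a, b) wrap_angle(a - b)

# logical mask of pixels (within `within` mask) falling in the sector
sector_mask <- function(sector, within) {
  h <- nrow(within); w <- ncol(within)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  ang <- atan2(ys - sector$apex[2], xs - sector$apex[1])
  within & (abs(angle_diff(ang, sector$direction)) <= sector$half_width)
}

# membership of points (n x 2) in a sector
points_in_sector <- function(pts, sector) {
  ang <- atan2(pts[, 2] - sector$apex[2], pts[, 1] - sector$apex[1])
  abs(angle_diff(ang, sector$direction)) <= sector$half_width
}
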