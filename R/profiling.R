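# Linescan intensity profiles and perinuclear/peripheral compartment
# scoring of endocytic cargo.

#' Linescan intensity profile from the plasma membrane inwards
#'
#' Samples image intensity along radial segments (see [radial_lines()]) at
#' regular steps, averaging over the perpendicular slab width of each
#' segment and then across segments at equal distance.  Distance 0 is the
#' plasma membrane; distance grows toward the nucleus.
#'
#' Intensities are bilinearly interpolated between pixel centers.
#'
#' @param image numeric intensity matrix.
#' @param segments list of `sampling_segment`s from [radial_lines()]; all
#'   must share the same nominal length.
#' @param step sampling step along the line, pixels.
#' @param channel channel name stored in the result (e.g. `"Tfn"`).
#' @return `intensity_profile` object: `distances` (pixels from the PM
#'   inward, starting at 0), `mean_intensity`, `n_lines_averaged`,
#'   `channel`.
#' @examples
#' img <- matrix(7, 50, 50)
#' roi <- cell_roi(circle_polygon(20, c(25, 25)), circle_polygon(7, c(25, 25)))
#' p <- linescan_profile(img, radial_lines(roi, 3, length = 10), step = 1)
#' all(p$mean_intensity == 7)
#' @export
linescan_profile <- function(image, segments, step = 1, channel = "ch1") {
  if (length(segments) == 0L) trk_stop("no-segments", "empty segment list")
  lens <- vapply(segments, function(s) s$length, 0)
  L <- min(lens)
  if (max(lens) - L > 1e-6 && max(lens - L) > step)
    L <- min(lens)  # profiles are averaged over the common support
  d <- seq(0, L, by = step)
  prof <- matrix(NA_real_, length(segments), length(d))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    u <- (s$end - s$start) / s$length        # unit vector, PM -> nucleus
    perp <- c(-u[2], u[1])
    w <- max(1L, as.integer(round(s$width)))
    offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
    acc <- numeric(length(d))
    for (o in offs) {
      px <- s$start[1] + d * u[1] + o * perp[1]
      py <- s$start[2] + d * u[2] + o * perp[2]
      if (any(px < 0 | px > ncol(image) | py < 0 | py > nrow(image)))
        trk_stop("out-of-bounds", "segment samples fall outside the image")
      acc <- acc + bilinear_sample(image, px, py)
    }
    prof[i, ] <- acc / length(offs)
  }
  structure(list(distances = d, mean_intensity = colMeans(prof),
                 n_lines_averaged = length(segments), channel = channel),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %s: %d points over %.0f px, average of %d lines\n",
              x$channel, length(x$distances), max(x$distances), x$n_lines_averaged))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  plot(x$distances, x$mean_intensity, type = "l",
       xlab = "distance from PM (px)", ylab = "mean intensity",
       main = x$channel, ...)
  invisible(x)
}

# bilinear interpolation at continuous (x, y) on the pixel-center grid
# (center of img[r, c] is (c - 0.5, r - 0.5)); within the outer half-pixel
# border the edge gradient is extrapolated so linear fields stay exact
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  gx <- x - 0.5
  gy <- y - 0.5
  c0 <- pmin(pmax(floor(gx), 0), w - 2); r0 <- pmin(pmax(floor(gy), 0), h - 2)
  fx <- gx - c0; fy <- gy - r0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Maximal compartment intensities of a cell
#'
#' Background-corrected maximal intensity of an image within the
#' perinuclear and peripheral masks, the per-cell statistic used to score
#' cargo distribution.
#'
#' @param image numeric intensity matrix matching the mask raster.
#' @param masks [build_compartment_masks()] output.
#' @param background `"median-outside"` (default; median intensity outside
#'   the cell mask), a non-negative constant, or `"none"`.
#' @param cell_id identifier carried into the result.
#' @return `compartment_score` object with `perinuclear_max`,
#'   `peripheral_max`, `background`, `cell_id` (and `label = NA` until
#'   [classify_cell()] is applied).
#' @export
compartment_max <- function(image, masks, background = "median-outside",
                            cell_id = NA_character_) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!all(dim(image) == dim(masks$cell)))
    trk_stop("bad-config", "image and masks have different raster sizes")
  if (!any(masks$perinuclear) || !any(masks$peripheral))
    trk_stop("empty-compartment", "a compartment mask is empty")
  bg <- if (identical(background, "median-outside")) {
    if (any(!masks$cell)) stats::median(image[!masks$cell]) else 0
  } else if (identical(background, "none")) 0 else as.numeric(background)
  corr <- function(v) max(pmax(v - bg, 0))
  structure(list(cell_id = cell_id,
                 perinuclear_max = corr(image[masks$perinuclear]),
                 peripheral_max  = corr(image[masks$peripheral]),
                 background = bg, label = NA_character_),
            class = "compartment_score")
}

#' @export
print.compartment_score <- function(x, ...) {
  cat(sprintf("<compartment_score> %s: perinuclear %.1f, peripheral %.1f (bg %.1f)%s\n",
              x$cell_id, x$perinuclear_max, x$peripheral_max, x$background,
              if (is.na(x$label)) "" else paste0(" -> ", x$label)))
  invisible(x)
}

#' Classify a cell as perinuclear or peripheral
#'
#' A cell is called perinuclear when its perinuclear maximal intensity
#' exceeds the peripheral one by more than the tie margin (and vice versa);
#' cells inside the margin — including all-zero cells — are ambiguous.
#'
#' @param score a `compartment_score` (or list with `perinuclear_max`,
#'   `peripheral_max`).
#' @param tie_margin relative margin; perinuclear requires
#'   `perinuclear_max > (1 + tie_margin) * peripheral_max`.
#' @return `"perinuclear"`, `"peripheral"` or `"ambiguous"`.
#' @export
classify_cell <- function(score, tie_margin = 0.1) {
  if (tie_margin < 0) trk_stop("bad-config", "tie_margin must be >= 0")
  pn <- score$perinuclear_max; pp <- score$peripheral_max
  if (pn < 0 || pp < 0) trk_stop("bad-config", "maxima must be non-negative")
  if (pn > (1 + tie_margin) * pp) "perinuclear"
  else if (pp > (1 + tie_margin) * pn) "peripheral"
  else "ambiguous"
}

#' Percentage of cells with perinuclear cargo
#'
#' @param labels character vector of per-cell labels from [classify_cell()].
#' @param experiment optional replicate/experiment id per cell; per-replicate
#'   fractions are then reported alongside the pooled one.
#' @return list with `fraction` (perinuclear / all cells; ambiguous cells
#'   count in the denominator), `counts` (table of labels) and
#'   `per_experiment` (data.frame, or NULL).
#' @export
percent_perinuclear <- function(labels, experiment = NULL) {
  if (length(labels) == 0L) trk_stop("no-cells", "no labels given")
  counts <- table(factor(labels, levels = c("perinuclear", "peripheral", "ambiguous")))
  per_exp <- NULL
  if (!is.null(experiment)) {
    per_exp <- do.call(rbind, lapply(split(labels, experiment), function(l)
      data.frame(n = length(l), fraction = mean(l == "perinuclear"))))
    per_exp <- data.frame(experiment = rownames(per_exp), per_exp, row.names = NULL)
  }
  list(fraction = unname(counts["perinuclear"]) / length(labels),
       counts = counts, per_experiment = per_exp)
}

#' Tidy per-cell compartment score table
#'
#' Convenience wrapper: scores, classifies and tabulates a list of cells.
#'
#' @param images list of intensity matrices, one per cell.
#' @param masks list of [build_compartment_masks()] outputs, same length.
#' @param tie_margin see [classify_cell()].
#' @param background see [compartment_max()].
#' @param cell_ids optional ids (default `cell_001`, ...).
#' @return data.frame `cell_id`, `perinuclear_max`, `peripheral_max`,
#'   `background`, `label`.
#' @export
compartment_score_table <- function(images, masks, tie_margin = 0.1,
                                    background = "median-outside",
                                    cell_ids = NULL) {
  stopifnot(length(images) == length(masks))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%03d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    sc <- compartment_max(images[[i]], masks[[i]], background, cell_ids[i])
    data.frame(cell_id = sc$cell_id, perinuclear_max = sc$perinuclear_max,
               peripheral_max = sc$peripheral_max, background = sc$background,
               label = classify_cell(sc, tie_margin))
  })
  do.call(rbind, rows)
}
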