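# Focal-adhesion particle analysis, Golgi area, and sector-based
# front-rear polarity scoring.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass.
label8 <- function(binary) {
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary))))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    roots <- vapply(seq_len(n), find, 0L)
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

# resolve a threshold spec within a mask
resolve_threshold <- function(image, mask, threshold_method, threshold) {
  if (identical(threshold_method, "fixed")) {
    if (is.null(threshold)) trk_stop("bad-config", "fixed thresholding needs a threshold")
    threshold
  } else otsu_threshold(image[mask])
}

#' Segment puncta (particle analysis)
#'
#' Thresholds an image within the cell mask, labels 8-connected components,
#' discards those below `min_size`, and reports per-particle geometry plus
#' the per-cell count and mean area — the standard focal-adhesion particle
#' analysis.
#'
#' @param image numeric intensity matrix.
#' @param cell_mask logical matrix restricting the analysis.
#' @param threshold_method `"otsu"` (within the mask) or `"fixed"`.
#' @param threshold fixed threshold (intensity units) when
#'   `threshold_method = "fixed"`.
#' @param min_size minimum particle area in px^2 (default 4).
#' @param pixel_size micrometres per pixel; areas in um^2 are added when
#'   given.
#' @param cell_id identifier carried into the table.
#' @return `particle_table` object: data.frame of particles (`id`, `x`,
#'   `y`, `area_px2`, `area_um2`, `mean_intensity`) with attributes
#'   `count`, `mean_area_px2`, `total_area_px2`.  No suprathreshold pixels
#'   gives an empty table with count 0.
#' @export
segment_puncta <- function(image, cell_mask, threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_size = 4, pixel_size = 1,
                           cell_id = NA_character_) {
  threshold_method <- match.arg(threshold_method)
  if (!any(cell_mask)) trk_stop("bad-config", "cell mask is empty")
  if (min_size < 1) trk_stop("bad-config", "min_size must be >= 1")
  thr <- resolve_threshold(image, cell_mask, threshold_method, threshold)
  fg <- cell_mask & image > thr
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      area_px2 = numeric(), area_um2 = numeric(),
                      mean_intensity = numeric())
  if (!any(fg)) return(particle_table(empty, thr, pixel_size, cell_id))
  lab <- label8(fg)
  ids <- seq_len(max(lab))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- ids[areas >= min_size]
  if (!length(keep)) return(particle_table(empty, thr, pixel_size, cell_id))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  sel <- l %in% keep
  l <- l[sel]; idx <- idx[sel, , drop = FALSE]
  vals <- image[cbind(idx[, 1], idx[, 2])]
  xc <- tapply(idx[, 2] - 0.5, l, mean)   # pixel-center x
  yc <- tapply(idx[, 1] - 0.5, l, mean)
  mi <- tapply(vals, l, mean)
  df <- data.frame(id = seq_along(keep), x = as.numeric(xc), y = as.numeric(yc),
                   area_px2 = areas[keep],
                   area_um2 = areas[keep] * pixel_size^2,
                   mean_intensity = as.numeric(mi))
  particle_table(df, thr, pixel_size, cell_id)
}

particle_table <- function(df, threshold, pixel_size, cell_id) {
  structure(df, class = c("particle_table", "data.frame"),
            count = nrow(df),
            mean_area_px2 = if (nrow(df)) mean(df$area_px2) else NA_real_,
            total_area_px2 = sum(df$area_px2),
            threshold = threshold, pixel_size = pixel_size, cell_id = cell_id)
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table> %d particles, mean area %.1f px^2 (threshold %.3g)\n",
              attr(x, "count"), attr(x, "mean_area_px2"), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Golgi (suprathreshold structure) area
#'
#' Total suprathreshold area of a marker channel within the cell.
#'
#' @inheritParams segment_puncta
#' @return list `area_px2`, `area_um2`, `threshold`.
#' @export
golgi_area <- function(image, cell_mask, threshold_method = c("otsu", "fixed"),
                       threshold = NULL, pixel_size = 1) {
  threshold_method <- match.arg(threshold_method)
  if (!any(cell_mask)) trk_stop("bad-config", "cell mask is empty")
  thr <- resolve_threshold(image, cell_mask, threshold_method, threshold)
  a <- sum(cell_mask & image > thr)
  list(area_px2 = a, area_um2 = a * pixel_size^2, threshold = thr)
}

#' Front-rear polarity score of a cell
#'
#' Fraction of a structure's signal falling inside the front sector
#' ([front_sector()]).  With `basis = "intensity"` the fraction is of total
#' suprathreshold intensity; with `basis = "count"` it is the fraction of
#' particle centroids.  A cell is polarized when the fraction strictly
#' exceeds 0.5 (a tie at exactly 0.5 is not polarized).
#'
#' @param x either an intensity matrix (intensity basis; give `cell_mask`)
#'   or a [segment_puncta()] `particle_table` (count basis).
#' @param sector a `sector_region` from [front_sector()].
#' @param basis `"intensity"` or `"count"`.
#' @param cell_mask logical matrix (intensity basis only).
#' @param threshold_method,threshold as in [segment_puncta()].
#' @param cell_id identifier carried into the result.
#' @return `polarity_result`: `cell_id`, `in_sector_fraction`, `polarized`,
#'   `basis`.
#' @export
polarity_score <- function(x, sector, basis = c("intensity", "count"),
                           cell_mask = NULL,
                           threshold_method = c("otsu", "fixed"),
                           threshold = NULL, cell_id = NA_character_) {
  basis <- match.arg(basis)
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(sector, "sector_region"))
  if (basis == "count" || inherits(x, "particle_table")) {
    if (!inherits(x, "particle_table"))
      trk_stop("bad-config", "count basis needs a particle_table")
    if (nrow(x) == 0L) trk_stop("no-structures", "no particles to score")
    frac <- mean(points_in_sector(cbind(x$x, x$y), sector))
    basis <- "count"
  } else {
    if (is.null(cell_mask)) trk_stop("bad-config", "intensity basis needs cell_mask")
    thr <- resolve_threshold(x, cell_mask, threshold_method, threshold)
    fg <- cell_mask & x > thr
    if (!any(fg)) trk_stop("no-structures", "no suprathreshold structure signal")
    insec <- sector_mask(sector, fg)
    frac <- sum(x[insec]) / sum(x[fg])
  }
  structure(list(cell_id = cell_id, in_sector_fraction = frac,
                 polarized = frac > 0.5, basis = basis),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity_result> %s: %.1f%% of %s in sector -> %s\n",
              x$cell_id, 100 * x$in_sector_fraction, x$basis,
              if (x$polarized) "polarized" else "not polarized"))
  invisible(x)
}

#' Percentage of polarized cells
#'
#' @param results list of `polarity_result`s (or a logical vector of
#'   polarized calls).
#' @param experiment optional replicate id per cell.
#' @return list `fraction`, `n`, `per_experiment` (data.frame or NULL).
#' @export
percent_polarized <- function(results, experiment = NULL) {
  if (length(results) == 0L) trk_stop("no-cells", "no polarity results")
  pol <- if (is.logical(results)) results
         else vapply(results, function(r) isTRUE(r$polarized), NA)
  per_exp <- NULL
  if (!is.null(experiment)) {
    per_exp <- do.call(rbind, lapply(split(pol, experiment), function(l)
      data.frame(n = length(l), fraction = mean(l))))
    per_exp <- data.frame(experiment = rownames(per_exp), per_exp, row.names = NULL)
  }
  list(fraction = mean(pol), n = length(pol), per_experiment = per_exp)
}
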