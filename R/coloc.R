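# Manders colocalization coefficients and colocalized-fraction time
# courses (cargo vs organelle marker).

#' Masked Otsu threshold
#'
#' Otsu's between-class-variance threshold computed from the intensity
#' histogram restricted to a region of interest (the whole-image Otsu of
#' common image software cannot be restricted to a cell mask).
#'
#' @param values numeric vector of intensities (already masked).
#' @param levels number of histogram bins.
#' @return threshold on the intensity scale; pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) trk_stop("empty-channel", "no pixels to threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])  # flat region: nothing above threshold
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu <- mu1[levels]
  bc <- (mu * w1 - mu1)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' Manders colocalization coefficients
#'
#' `m1` is the fraction of channel-1 signal that overlaps channel-2
#' foreground; `m2` the converse.  In `pixel-count` mode (default) signal
#' means suprathreshold pixels; in `intensity-weighted` mode pixels are
#' weighted by channel intensity.  Computation is restricted to the cell
#' mask when one is given.
#'
#' @param ch1,ch2 numeric intensity matrices of equal size.
#' @param mask optional logical matrix restricting the analysis.
#' @param threshold_method `"otsu"` (per channel, within the mask) or
#'   `"fixed"` (give `thresholds`).
#' @param thresholds numeric length-2 `(t1, t2)` for `"fixed"`.
#' @param mode `"pixel-count"` or `"intensity-weighted"`.
#' @return `coloc_result` object: `m1`, `m2` (NA with a flag when a channel
#'   has no suprathreshold pixels), `threshold_1`, `threshold_2`, `mode`,
#'   `empty_channel`.
#' @examples
#' a <- matrix(0, 8, 8); a[2:4, 2:4] <- 100
#' manders(a, a, threshold_method = "fixed", thresholds = c(50, 50))$m1  # 1
#' @export
manders <- function(ch1, ch2, mask = NULL,
                    threshold_method = c("otsu", "fixed"),
                    thresholds = NULL,
                    mode = c("pixel-count", "intensity-weighted")) {
  threshold_method <- match.arg(threshold_method)
  mode <- match.arg(mode)
  if (!all(dim(ch1) == dim(ch2))) trk_stop("bad-config", "channel rasters differ in shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  if (!any(mask)) trk_stop("bad-config", "mask is empty")
  if (threshold_method == "fixed") {
    if (is.null(thresholds) || length(thresholds) != 2)
      trk_stop("bad-config", "fixed thresholding needs thresholds = c(t1, t2)")
    t1 <- thresholds[1]; t2 <- thresholds[2]
  } else {
    t1 <- otsu_threshold(ch1[mask])
    t2 <- otsu_threshold(ch2[mask])
  }
  f1 <- mask & ch1 > t1
  f2 <- mask & ch2 > t2
  coef_of <- function(fa, fb, a) {
    if (!any(fa)) return(NA_real_)
    if (mode == "pixel-count") sum(fa & fb) / sum(fa)
    else sum(a[fa & fb]) / sum(a[fa])
  }
  m1 <- coef_of(f1, f2, ch1)
  m2 <- coef_of(f2, f1, ch2)
  structure(list(m1 = m1, m2 = m2, threshold_1 = t1, threshold_2 = t2,
                 mode = mode,
                 empty_channel = c(ch1 = !any(f1), ch2 = !any(f2))),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> m1 = %.3f, m2 = %.3f (%s; thresholds %.3g / %.3g)%s\n",
              x$m1, x$m2, x$mode, x$threshold_1, x$threshold_2,
              if (any(x$empty_channel)) " [empty channel]" else ""))
  invisible(x)
}

#' Colocalized fraction of cargo with a marker over time
#'
#' For each time point and cell, the fraction of cargo signal overlapping
#' the marker channel (`m1` of [manders()]), the statistic behind
#' cargo-vs-Golgi and MET-vs-endosomal-marker time courses.
#'
#' @param cargo_frames,marker_frames lists of intensity matrices (one per
#'   time point), or lists of such lists (outer index = cell).
#' @param masks a logical matrix, or list of matrices (one per cell).
#' @param times numeric time points (minutes), same length as the frame
#'   lists.
#' @param marker marker name stored in the table.
#' @param ... passed to [manders()] (thresholds, mode, ...).
#' @return `coloc_timecourse`: data.frame `cell_id`, `time_min`, `marker`,
#'   `fraction` (= m1), `m2`, `threshold_1`, `threshold_2`.
#' @export
fraction_colocalized_over_time <- function(cargo_frames, marker_frames, masks,
                                           times, marker = "marker", ...) {
  per_cell <- is.list(cargo_frames[[1]])
  cells <- if (per_cell) seq_along(cargo_frames) else 1L
  rows <- list()
  for (ci in cells) {
    cf <- if (per_cell) cargo_frames[[ci]] else cargo_frames
    mf <- if (per_cell) marker_frames[[ci]] else marker_frames
    mk <- if (is.list(masks)) masks[[ci]] else masks
    if (length(cf) != length(mf) || length(cf) != length(times))
      trk_stop("length-mismatch", "cargo frames, marker frames and times must align")
    if (is.unsorted(times, strictly = TRUE))
      trk_stop("bad-timebase", "time points must be strictly increasing")
    for (ti in seq_along(times)) {
      r <- manders(cf[[ti]], mf[[ti]], mask = mk, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("cell_%03d", ci), time_min = times[ti],
        marker = marker, fraction = r$m1, m2 = r$m2,
        threshold_1 = r$threshold_1, threshold_2 = r$threshold_2)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("coloc_timecourse", class(out))
  out
}
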