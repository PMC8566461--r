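# Trajectory statistics, endosomal maturation time series, and the
# plate/densitometry kinetics (endocytosed %, recycled fraction, protein
# degradation half-life).

#' Trajectory statistics of a single track
#'
#' Speed is total path length over elapsed time; net displacement is the
#' straight start-to-end distance; directionality (directional persistence)
#' is their ratio net/path, in `[0, 1]` and defined as 0 for a track that
#' never moves.
#'
#' @param track data.frame with columns `t`, `x`, `y` (>= 2 rows, `t`
#'   strictly increasing).
#' @return `track_stats` object: `speed`, `net_displacement`,
#'   `path_length`, `directionality`, `n_points`, `duration`.
#' @examples
#' tr <- data.frame(t = 0:9, x = 2 * (0:9), y = 0)
#' track_stats(tr)$speed           # 2
#' track_stats(tr)$directionality  # 1
#' @export
track_stats <- function(track) {
  if (nrow(track) < 2L) trk_stop("track-too-short", "need at least 2 points")
  if (is.unsorted(track$t, strictly = TRUE))
    trk_stop("bad-timebase", "t must be strictly increasing")
  if (!all(is.finite(track$x)) || !all(is.finite(track$y)))
    trk_stop("bad-timebase", "coordinates must be finite")
  dx <- diff(track$x); dy <- diff(track$y)
  steps <- sqrt(dx^2 + dy^2)
  path <- sum(steps)
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  dur <- track$t[nrow(track)] - track$t[1]
  structure(list(speed = path / dur, net_displacement = net,
                 path_length = path,
                 directionality = if (path > 0) net / path else 0,
                 n_points = nrow(track), duration = dur),
            class = "track_stats")
}

#' @export
print.track_stats <- function(x, ...) {
  cat(sprintf("<track_stats> %d pts over %g: speed %.3f, net %.2f, path %.2f, directionality %.3f\n",
              x$n_points, x$duration, x$speed, x$net_displacement,
              x$path_length, x$directionality))
  invisible(x)
}

#' Per-track statistics table
#'
#' @param tracks long data.frame `track_id`, `t`, `x`, `y` (e.g. from
#'   [read_tracks_csv()] or [simulate_tracks()]).
#' @return data.frame, one row per track: `track_id`, `speed`,
#'   `net_displacement`, `path_length`, `directionality`, `n_points`.
#' @export
track_stats_table <- function(tracks) {
  rows <- lapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$t), ]
    s <- track_stats(d)
    data.frame(track_id = d$track_id[1], speed = s$speed,
               net_displacement = s$net_displacement,
               path_length = s$path_length,
               directionality = s$directionality, n_points = s$n_points)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vesicle maturation intensity series from a movie
#'
#' Mean intensity over suprathreshold vesicle pixels within the cell, per
#' frame — increasing series report vesicle acidification when the probe
#' brightens at low pH.
#'
#' Frames with no vesicle pixels are recorded as missing (NA) and flagged.
#' The mean is background-corrected: the median of sub-threshold in-cell
#' pixels is subtracted, so a brightening probe is not diluted by the
#' constant camera offset.
#'
#' @param movie list of intensity matrices (frames).
#' @param cell_mask logical matrix.
#' @param vesicle_threshold intensity threshold defining vesicle pixels, or
#'   `"otsu"` (default; recomputed per frame within the cell mask, which
#'   keeps the suprathreshold fraction of each vesicle comparable as the
#'   probe brightens).
#' @param times numeric times (minutes); defaults to 0, 1, 2, ...
#' @param normalization `"raw"` or `"fold-over-t0"`.
#' @param cell_id identifier.
#' @return `maturation_series`: `cell_id`, `times`,
#'   `mean_vesicle_intensity` (NA where a frame has no vesicle pixels),
#'   `missing_frames`, `normalization`.
#' @export
maturation_series <- function(movie, cell_mask, vesicle_threshold = "otsu",
                              times = NULL,
                              normalization = c("raw", "fold-over-t0"),
                              cell_id = NA_character_) {
  normalization <- match.arg(normalization)
  if (length(movie) < 2L) trk_stop("bad-config", "need at least 2 frames")
  if (is.null(times)) times <- seq_along(movie) - 1
  if (is.unsorted(times, strictly = TRUE))
    trk_stop("bad-timebase", "times must be strictly increasing")
  otsu_mode <- identical(vesicle_threshold, "otsu")
  thr <- NA_real_
  vals <- vapply(movie, function(fr) {
    th <- if (otsu_mode) otsu_threshold(fr[cell_mask]) else vesicle_threshold
    thr <<- th
    sel <- cell_mask & fr > th
    if (!any(sel)) return(NA_real_)
    bg <- stats::median(fr[cell_mask & fr <= th])
    max(mean(fr[sel]) - bg, 0)
  }, 0)
  if (normalization == "fold-over-t0") {
    if (is.na(vals[1]) || vals[1] <= 0)
      trk_stop("zero-reference", "no vesicle signal at t0 to normalize by")
    vals <- vals / vals[1]
  }
  structure(list(cell_id = cell_id, times = times,
                 mean_vesicle_intensity = vals,
                 missing_frames = which(is.na(vals)),
                 normalization = normalization, threshold = thr),
            class = "maturation_series")
}

#' @export
print.maturation_series <- function(x, ...) {
  cat(sprintf("<maturation_series> %s: %d frames (%s), %d missing\n",
              x$cell_id, length(x$times), x$normalization,
              length(x$missing_frames)))
  invisible(x)
}

#' Endocytosed percentage from an in-cell ELISA plate
#'
#' Internalized cargo is expressed as a percentage of total surface-bound
#' cargo measured in parallel wells, after normalizing every well by its
#' total-protein (BCA) readout to correct for cell-number variation.
#'
#' @param plate data.frame as from [read_plate_csv()]/[simulate_plate()]:
#'   `condition`, `time_min`, `signal`, `bca_signal`, `role`.
#' @return data.frame `condition`, `time_min`, `percent_internalized`,
#'   `n_wells`.
#' @export
endocytosis_fraction <- function(plate) {
  ref <- plate[plate$role == "surface_total", ]
  if (nrow(ref) == 0L) trk_stop("zero-reference", "no surface_total wells")
  if (any(plate$bca_signal <= 0)) trk_stop("zero-reference", "non-positive BCA signal")
  out <- lapply(split(plate, plate$condition), function(d) {
    r <- d[d$role == "surface_total", ]
    if (nrow(r) == 0L) trk_stop("zero-reference", "condition lacks surface_total wells")
    ref_val <- mean(r$signal / r$bca_signal)
    if (ref_val <= 0) trk_stop("zero-reference", "surface-bound total is zero")
    s <- d[d$role == "sample", ]
    do.call(rbind, lapply(split(s, s$time_min), function(st)
      data.frame(condition = d$condition[1], time_min = st$time_min[1],
                 percent_internalized = 100 * mean(st$signal / st$bca_signal) / ref_val,
                 n_wells = nrow(st))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recycled fraction of internalized cargo
#'
#' The fraction of internalized cargo that is lost after the final
#' stripping step: `(internalized - remaining) / internalized`, clamped to
#' `[0, 1]` with a flag when measurement noise pushes it outside.
#'
#' @param internalized total internalized signal (> 0).
#' @param remaining_after_strip signal remaining after the final strip.
#' @return list `fraction`, `clamped`.
#' @export
recycled_fraction <- function(internalized, remaining_after_strip) {
  if (internalized <= 0) trk_stop("zero-internalized", "internalized signal must be > 0")
  raw <- (internalized - remaining_after_strip) / internalized
  list(fraction = min(max(raw, 0), 1), clamped = raw < 0 || raw > 1)
}

#' Recycled fraction per condition from a plate table
#'
#' Pairs `sample` wells (total internalized) with `strip_control` wells
#' (remaining after the final strip) per condition, BCA-normalized.
#'
#' @param plate plate data.frame (see [endocytosis_fraction()]).
#' @return data.frame `condition`, `recycled_fraction`, `clamped`, `n_wells`.
#' @export
recycled_fraction_table <- function(plate) {
  out <- lapply(split(plate, plate$condition), function(d) {
    s <- d[d$role == "sample", ]
    r <- d[d$role == "strip_control", ]
    if (nrow(s) == 0L || nrow(r) == 0L)
      trk_stop("zero-internalized", "condition lacks sample or strip_control wells")
    internal <- mean(s$signal / s$bca_signal)
    remain <- mean(r$signal / r$bca_signal)
    rf <- recycled_fraction(internal, remain)
    data.frame(condition = d$condition[1], recycled_fraction = rf$fraction,
               clamped = rf$clamped, n_wells = nrow(s) + nrow(r))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalized protein degradation curve with optional exponential fit
#'
#' Densitometric band intensities are divided by the loading control and
#' expressed as a percentage of the T=0 value.  Optionally a single
#' exponential `A * exp(-k t)` is least-squares fitted on the normalized
#' scale and the half-life `ln(2)/k` reported.
#'
#' @param times numeric times (minutes), T=0 must be present.
#' @param band band intensities.
#' @param control loading-control intensities (> 0).
#' @param fit fit the exponential (default TRUE).
#' @return `decay_curve`: `times`, `normalized_intensity` (percent of T=0),
#'   `fitted_half_life` (minutes, NA if not fitted), `rate_constant`,
#'   `fit` (the `nls` object or NULL).
#' @export
degradation_curve <- function(times, band, control, fit = TRUE) {
  if (length(times) != length(band) || length(times) != length(control))
    trk_stop("length-mismatch", "times, band and control must have equal length")
  if (any(control <= 0)) trk_stop("zero-loading-control", "loading control must be > 0")
  if (!any(times == 0)) trk_stop("bad-timebase", "a T=0 point is required")
  o <- order(times)
  times <- times[o]; band <- band[o]; control <- control[o]
  ratio <- band / control
  norm <- 100 * ratio / ratio[times == 0][1]
  half_life <- NA_real_; k <- NA_real_; fobj <- NULL
  if (fit) {
    # start values from a log-linear regression on positive points
    pos <- norm > 0
    lf <- stats::lm(log(norm[pos]) ~ times[pos])
    k0 <- max(-stats::coef(lf)[2], 1e-6)
    fobj <- minpack.lm::nlsLM(norm ~ A * exp(-k * times),
                              start = list(A = norm[1], k = k0),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- stats::coef(fobj)[["k"]]
    half_life <- log(2) / k
  }
  structure(list(times = times, normalized_intensity = norm,
                 fitted_half_life = half_life, rate_constant = k, fit = fobj),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d points; T=0 at 100%%%s\n", length(x$times),
              if (is.na(x$fitted_half_life)) ""
              else sprintf("; fitted half-life %.1f min", x$fitted_half_life)))
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, ...) {
  plot(x$times, x$normalized_intensity, xlab = "time (min)",
       ylab = "% of initial", ylim = c(0, max(100, x$normalized_intensity)), ...)
  if (!is.na(x$fitted_half_life)) {
    tt <- seq(min(x$times), max(x$times), length.out = 100)
    graphics::lines(tt, stats::predict(x$fit, list(times = tt)))
  }
  invisible(x)
}
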