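# Orchestration and statistics: end-to-end runs from a config with a
# machine-readable manifest, and the group comparisons used throughout
# (unpaired t-test, one-way ANOVA, Spearman correlation).

#' Compare groups of per-cell values
#'
#' The statistical surface used for every readout: unpaired two-tailed
#' Student's t-test for two groups, one-way ANOVA for more, and Spearman
#' rank correlation for paired continuous observations.  Group means are
#' reported with SEM, matching the convention of dot-plot figures.
#'
#' @param x for `"t"`/`"anova"`: named list of numeric vectors (one per
#'   group); for `"spearman"`: list of two equal-length vectors (x, y).
#' @param test `"t"`, `"anova"` or `"spearman"`.
#' @param paired paired t-test (default FALSE, the standard design).
#' @return `group_comparison`: `summary` data.frame (group, n, mean, sem),
#'   `test`, `statistic`, `p_value`, `flag` (e.g. `zero-variance`).
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))$p_value
#' @export
compare_groups <- function(x, test = c("t", "anova", "spearman"),
                           paired = FALSE) {
  test <- match.arg(test)
  if (!is.list(x)) trk_stop("bad-config", "x must be a list of numeric vectors")
  ns <- lengths(x)
  if (test == "spearman") {
    if (length(x) != 2 || ns[1] != ns[2] || ns[1] < 3)
      trk_stop("insufficient-data", "spearman needs two equal vectors with >= 3 pairs")
  } else if (any(ns < 2)) {
    trk_stop("insufficient-data", "each group needs n >= 2")
  }
  if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
  summ <- data.frame(group = names(x), n = as.integer(ns),
                     mean = vapply(x, mean, 0),
                     sem = vapply(x, function(v) stats::sd(v) / sqrt(length(v)), 0),
                     row.names = NULL)
  flag <- NA_character_; statistic <- NA_real_; p <- NA_real_
  if (test == "t") {
    if (length(x) != 2) trk_stop("insufficient-data", "t-test needs exactly 2 groups")
    if (stats::sd(x[[1]]) == 0 && stats::sd(x[[2]]) == 0) {
      flag <- "zero-variance"
    } else {
      ht <- stats::t.test(x[[1]], x[[2]], paired = paired, var.equal = FALSE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else if (test == "anova") {
    vals <- unlist(x, use.names = FALSE)
    grp <- factor(rep(names(x), ns))
    if (stats::sd(vals) == 0) {
      flag <- "zero-variance"
    } else {
      a <- stats::anova(stats::aov(vals ~ grp))
      statistic <- a[["F value"]][1]; p <- a[["Pr(>F)"]][1]
    }
  } else {
    ht <- suppressWarnings(stats::cor.test(x[[1]], x[[2]], method = "spearman",
                                           alternative = "two.sided"))
    statistic <- unname(ht$estimate)  # Spearman R
    p <- ht$p.value
  }
  structure(list(summary = summ, test = test, statistic = statistic,
                 p_value = p, paired = paired, flag = flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p_value,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(x$summary)
  invisible(x)
}

#' Run an analysis from a configuration
#'
#' Orchestrates a complete analysis: validates the configuration, generates
#' synthetic inputs or loads real ones, runs the selected measurement
#' modules, and writes tidy CSV result tables plus a JSON run manifest
#' (parameters, package version, input/output hashes) to the output
#' directory.  Runs are deterministic given (config, seed); cells that fail
#' are skipped and logged with a reason code.
#'
#' Supported `analysis` values: `"simulate"`, `"profile"`, `"coloc"`,
#' `"morpho"`, `"polarity"`, `"tracks"`, `"kinetics"`, `"stats"`, `"demo"`.
#' `"demo"` is the end-to-end two-condition experiment: an epithelial-like
#' (`p_perinuclear = 0.2`) versus mesenchymal-like (`p_perinuclear = 0.8`)
#' scene pair, scored, classified and compared with a t-test.
#'
#' @param config named list (or path to a YAML/JSON file) with at least
#'   `analysis` and `outdir`; `seed` defaults to 1.  Exactly one of
#'   simulator parameters (`sim`) or real input paths (`inputs`) per run.
#'   See the vignette for per-analysis fields.
#' @return invisibly, a list with `tables` (paths of written CSVs),
#'   `manifest` (path) and `log` (data.frame of skipped units).
#' @export
run_analysis <- function(config) {
  cfg <- load_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(unit = character(), reason = character())
  tables <- character(0)

  emit <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".csv"))
    write_table_csv(df, p)
    tables[[name]] <<- p
    p
  }

  set.seed(cfg$seed)
  res <- switch(cfg$analysis,
    simulate = run_simulate(cfg, outdir),
    profile = run_profile(cfg, emit, log),
    coloc = run_coloc(cfg, emit),
    morpho = run_morpho(cfg, emit, log),
    polarity = run_polarity(cfg, emit, log),
    tracks = run_tracks(cfg, emit),
    kinetics = run_kinetics(cfg, emit),
    stats = run_stats(cfg, outdir),
    demo = run_demo(cfg, emit),
    trk_stop("bad-config", paste("unknown analysis:", cfg$analysis)))
  if (!is.null(res$tables)) tables <- c(tables, res$tables)
  if (!is.null(res$log)) log <- rbind(log, res$log)

  manifest <- list(
    package = "traffickr",
    version = as.character(utils::packageVersion("traffickr")),
    analysis = cfg$analysis, seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("outdir"))],
    outputs = as.list(vapply(tables, function(p) unname(tools::md5sum(p)), "")),
    inputs = if (!is.null(cfg$inputs))
      as.list(vapply(unlist(cfg$inputs), function(p) unname(tools::md5sum(p)), ""))
      else NULL,
    skipped = if (nrow(log)) log else NULL)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(list(tables = tables, manifest = mpath, log = log, result = res$result))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) trk_stop("missing-input", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  if (is.null(config$analysis)) trk_stop("bad-config", "config needs an 'analysis'")
  if (is.null(config$outdir)) trk_stop("bad-config", "config needs an 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$sim) && !is.null(config$inputs))
    trk_stop("bad-config", "give either simulator parameters or real inputs, not both")
  # fail fast on missing input files, before any computation
  for (p in unlist(config$inputs)) if (!file.exists(p)) trk_stop("missing-input", p)
  config
}

scene_from_cfg <- function(cfg) {
  sim <- cfg$sim
  sim$seed <- if (!is.null(sim$seed)) sim$seed else cfg$seed
  simulate_scene(do.call(scene_config, sim))
}

# load per-cell images + rois either from the simulator or from files
load_cells <- function(cfg, channel = "cargo") {
  if (!is.null(cfg$sim)) {
    sc <- scene_from_cfg(cfg)
    list(images = lapply(sc$cells, function(cl) cl$images[[channel]]),
         rois = sc$rois, scene = sc)
  } else {
    rois <- read_roi_json(cfg$inputs$rois)
    img <- read_image_tiff(cfg$inputs$images)
    if (is.matrix(img)) img <- list(img)
    if (length(img) != length(rois))
      trk_stop("length-mismatch", "image pages and ROI records differ in number")
    names(img) <- names(rois)
    list(images = img, rois = rois, scene = NULL)
  }
}

run_simulate <- function(cfg, outdir) {
  sc <- scene_from_cfg(cfg)
  paths <- write_scene(sc, outdir)
  tr <- simulate_tracks(n_tracks = cfg$n_tracks %||% 50, seed = cfg$seed)
  pl <- simulate_plate(true_uptake = cfg$true_uptake %||% 0.3, seed = cfg$seed)
  tp <- file.path(outdir, "tracks.csv"); write_table_csv(tr, tp)
  pp <- file.path(outdir, "plate.csv"); write_table_csv(pl, pp)
  list(tables = c(paths["rois"], tracks = tp, plate = pp), result = sc)
}

run_profile <- function(cfg, emit, log) {
  cl <- load_cells(cfg)
  prof_rows <- list(); score_rows <- list()
  for (id in names(cl$rois)) {
    ok <- tryCatch({
      roi <- cl$rois[[id]]; img <- cl$images[[id]]
      masks <- build_compartment_masks(roi,
        perinuclear_band = cfg$perinuclear_band %||% 0.25,
        peripheral_band = cfg$peripheral_band %||% 0.15,
        dim = c(ncol(img), nrow(img)))
      segs <- radial_lines(roi, n_lines = cfg$n_lines %||% 3,
                           width = cfg$line_width %||% 3)
      pr <- linescan_profile(img, segs, step = cfg$step %||% 1,
                             channel = cfg$channel %||% "cargo")
      prof_rows[[id]] <- data.frame(cell_id = id, channel = pr$channel,
                                    distance_px = pr$distances,
                                    intensity = pr$mean_intensity)
      sc <- compartment_max(img, masks, cell_id = id)
      score_rows[[id]] <- data.frame(
        cell_id = id, perinuclear_max = sc$perinuclear_max,
        peripheral_max = sc$peripheral_max, background = sc$background,
        label = classify_cell(sc, tie_margin = cfg$tie_margin %||% 0.1))
      TRUE
    }, traffickr_error = function(e) {
      log <<- rbind(log, data.frame(unit = id, reason = conditionMessage(e)))
      FALSE
    })
  }
  if (!length(score_rows)) trk_stop("no-cells", "every cell failed")
  scores <- do.call(rbind, score_rows)
  emit(do.call(rbind, prof_rows), "profiles")
  emit(scores, "compartment_scores")
  pct <- percent_perinuclear(scores$label)
  emit(data.frame(n_cells = nrow(scores), fraction_perinuclear = pct$fraction),
       "percent_perinuclear")
  list(result = list(scores = scores, percent = pct), log = log)
}

run_coloc <- function(cfg, emit) {
  if (!is.null(cfg$sim)) {
    fr <- simulate_coloc_frames(overlaps = cfg$overlaps %||% c(0.1, 0.4, 0.7),
                                seed = cfg$seed)
    tc <- fraction_colocalized_over_time(fr$cargo_frames, fr$marker_frames,
                                         fr$mask, times = cfg$times %||%
                                           (seq_along(fr$cargo_frames) * 10 - 10),
                                         marker = cfg$marker %||% "GM130")
  } else {
    cargo <- read_image_tiff(cfg$inputs$cargo)
    marker <- read_image_tiff(cfg$inputs$marker)
    if (is.matrix(cargo)) { cargo <- list(cargo); marker <- list(marker) }
    rois <- read_roi_json(cfg$inputs$rois)
    mask <- Reduce(`|`, lapply(rois, function(r)
      rasterize_polygon(r$cell_outline, ncol(cargo[[1]]), nrow(cargo[[1]]))))
    tc <- fraction_colocalized_over_time(cargo, marker, mask,
                                         times = cfg$times %||% (seq_along(cargo) - 1),
                                         marker = cfg$marker %||% "marker")
  }
  emit(as.data.frame(tc), "coloc_timecourse")
  list(result = tc)
}

run_morpho <- function(cfg, emit, log) {
  cl <- load_cells(cfg, channel = "fa")
  rows <- list(); parts <- list()
  for (id in names(cl$rois)) {
    tryCatch({
      img <- cl$images[[id]]; roi <- cl$rois[[id]]
      cmask <- rasterize_polygon(roi$cell_outline, ncol(img), nrow(img))
      pt <- segment_puncta(img, cmask, min_size = cfg$min_size %||% 4,
                           pixel_size = roi$pixel_size, cell_id = id)
      parts[[id]] <- if (nrow(pt)) data.frame(cell_id = id, as.data.frame(pt)) else NULL
      rows[[id]] <- data.frame(cell_id = id, count = attr(pt, "count"),
                               mean_area_px2 = attr(pt, "mean_area_px2"))
    }, traffickr_error = function(e) {
      log <<- rbind(log, data.frame(unit = id, reason = conditionMessage(e)))
    })
  }
  emit(do.call(rbind, parts), "particles")
  emit(do.call(rbind, rows), "fa_summary")
  list(result = do.call(rbind, rows), log = log)
}

run_polarity <- function(cfg, emit, log) {
  cl <- load_cells(cfg, channel = "fa")
  rows <- list()
  for (id in names(cl$rois)) {
    tryCatch({
      img <- cl$images[[id]]; roi <- cl$rois[[id]]
      cmask <- rasterize_polygon(roi$cell_outline, ncol(img), nrow(img))
      sec <- front_sector(roi,
                          direction = cfg$front_direction %||% 0,
                          half_width = cfg$front_half_width %||% (pi / 3))
      ps <- polarity_score(img, sec, basis = cfg$basis %||% "intensity",
                           cell_mask = cmask, cell_id = id)
      rows[[id]] <- data.frame(cell_id = id,
                               in_sector_fraction = ps$in_sector_fraction,
                               polarized = ps$polarized, basis = ps$basis)
    }, traffickr_error = function(e) {
      log <<- rbind(log, data.frame(unit = id, reason = conditionMessage(e)))
    })
  }
  df <- do.call(rbind, rows)
  emit(df, "polarity")
  pp <- percent_polarized(df$polarized)
  emit(data.frame(n_cells = pp$n, fraction_polarized = pp$fraction),
       "percent_polarized")
  list(result = df, log = log)
}

run_tracks <- function(cfg, emit) {
  tr <- if (!is.null(cfg$inputs$tracks)) read_tracks_csv(cfg$inputs$tracks)
        else do.call(simulate_tracks, c(cfg$sim, list(seed = cfg$seed)))
  st <- track_stats_table(tr)
  emit(st, "track_stats")
  list(result = st)
}

run_kinetics <- function(cfg, emit) {
  tables <- list(); result <- list()
  plate <- if (!is.null(cfg$inputs$plate)) read_plate_csv(cfg$inputs$plate)
           else if (!is.null(cfg$sim$plate)) do.call(simulate_plate, cfg$sim$plate)
  if (!is.null(plate)) {
    result$endocytosis <- endocytosis_fraction(plate)
    emit(result$endocytosis, "endocytosis")
    result$recycling <- recycled_fraction_table(plate)
    emit(result$recycling, "recycling")
  }
  dens <- if (!is.null(cfg$inputs$densitometry)) utils::read.csv(cfg$inputs$densitometry)
          else if (!is.null(cfg$sim$densitometry)) do.call(simulate_densitometry, cfg$sim$densitometry)
  if (!is.null(dens)) {
    dc <- degradation_curve(dens$time_min, dens$band, dens$control)
    result$decay <- data.frame(time_min = dc$times,
                               normalized_pct = dc$normalized_intensity,
                               fitted_half_life = dc$fitted_half_life)
    emit(result$decay, "degradation")
  }
  if (is.null(plate) && is.null(dens))
    trk_stop("bad-config", "kinetics needs a plate and/or densitometry input")
  list(result = result)
}

run_stats <- function(cfg, outdir) {
  df <- utils::read.csv(cfg$inputs$values)
  groups <- split(df$value, df$group)
  gc <- compare_groups(groups, test = cfg$test %||% "t")
  p <- file.path(outdir, "comparison.csv")
  write_table_csv(cbind(gc$summary,
                        test = gc$test, statistic = gc$statistic,
                        p_value = gc$p_value), p)
  list(tables = c(comparison = p), result = gc)
}

run_demo <- function(cfg, emit) {
  n <- cfg$n_cells %||% 30
  score_one <- function(p, seed, label) {
    sc <- simulate_scene(scene_config(n_cells = n, p_perinuclear = p, seed = seed))
    masks <- lapply(sc$cells, function(cl)
      build_compartment_masks(cl$roi, dim = dim(cl$images$cargo)[c(2, 1)]))
    df <- compartment_score_table(lapply(sc$cells, function(cl) cl$images$cargo),
                                  masks, cell_ids = names(sc$cells))
    df$condition <- label
    df
  }
  e <- score_one(0.2, cfg$seed, "epithelial_like")
  m <- score_one(0.8, cfg$seed + 1000L, "mesenchymal_like")
  both <- rbind(e, m)
  emit(both, "demo_scores")
  cmp_pn <- compare_groups(list(epithelial_like = e$perinuclear_max,
                                mesenchymal_like = m$perinuclear_max))
  cmp_pp <- compare_groups(list(epithelial_like = e$peripheral_max,
                                mesenchymal_like = m$peripheral_max))
  comp <- data.frame(
    readout = c("perinuclear_max", "peripheral_max"),
    mean_epithelial = c(cmp_pn$summary$mean[1], cmp_pp$summary$mean[1]),
    mean_mesenchymal = c(cmp_pn$summary$mean[2], cmp_pp$summary$mean[2]),
    t_statistic = c(cmp_pn$statistic, cmp_pp$statistic),
    p_value = c(cmp_pn$p_value, cmp_pp$p_value))
  emit(comp, "demo_comparison")
  pct <- data.frame(
    condition = c("epithelial_like", "mesenchymal_like"),
    fraction_perinuclear = c(percent_perinuclear(e$label)$fraction,
                             percent_perinuclear(m$label)$fraction))
  emit(pct, "demo_percent_perinuclear")
  list(result = list(scores = both, comparison = comp, percent = pct))
}

#' Re-run an analysis from its manifest
#'
#' Reads a run manifest written by [run_analysis()] and re-executes the run
#' with the stored configuration and seed into a new directory, which
#' reproduces every CSV byte-for-byte.
#'
#' @param manifest_path path to `manifest.json`.
#' @param outdir output directory for the re-run.
#' @return as [run_analysis()].
#' @export
run_from_manifest <- function(manifest_path, outdir) {
  m <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  cfg <- m$config
  cfg$analysis <- m$analysis
  cfg$seed <- m$seed
  cfg$outdir <- outdir
  run_analysis(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
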