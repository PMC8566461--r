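# Synthetic-scene generator: multi-channel still scenes, time-lapse
# movies, track tables and plate/densitometry tables with known ground
# truth.  Every output is reproducible bit-exactly from (config, seed).

#' Scene generator configuration
#'
#' Validated parameter set for [simulate_scene()].  Cells are ellipses with
#' a low-order Fourier boundary perturbation; cargo puncta are isotropic
#' Gaussians whose radial position is drawn from a perinuclear band with
#' probability `p_perinuclear`, otherwise from a peripheral band.
#'
#' @param n_cells number of cells (each rendered in its own tile).
#' @param cell_radius length-2 range of mean cell radii (px).
#' @param axis_ratio length-2 range of ellipse axis ratios.
#' @param boundary_wobble relative amplitude of the Fourier boundary
#'   perturbation (0 = smooth ellipse).
#' @param nucleus_fraction nucleus radius as a fraction of the cell radius.
#' @param n_puncta cargo puncta per cell.
#' @param puncta_amplitude median punctum peak amplitude (counts); per-punctum
#'   amplitudes are log-normal around it.
#' @param amplitude_sdlog log-sd of the punctum amplitude distribution.
#' @param psf_sigma Gaussian PSF sigma (px).
#' @param p_perinuclear probability a punctum is perinuclear.
#' @param dapi_intensity nucleus fill intensity of the DAPI channel.
#' @param golgi_area_px2 target Golgi blob area (px^2).
#' @param golgi_amplitude Golgi fill amplitude.
#' @param golgi_front_bias probability the Golgi sits inside the front
#'   sector; `NULL` places it uniformly around the nucleus.
#' @param fa_count focal-adhesion puncta per cell (0 disables the channel).
#' @param fa_mean_area mean FA area (px^2); per-FA areas are normal with
#'   CV `fa_area_cv`, truncated at 9 px^2.
#' @param fa_area_cv coefficient of variation of FA areas.
#' @param fa_amplitude FA fill amplitude.
#' @param fa_front_bias probability an FA punctum is placed inside the
#'   front sector; `NULL` = uniform placement around the cell edge.
#' @param fa_polarized_prob per-cell polarization probability: a polarized
#'   cell places all FAs in the front sector, an unpolarized one uniformly.
#'   Overrides `fa_front_bias`.  `NULL` disables.
#' @param front_direction front direction (radians).
#' @param front_half_width front sector half-width (radians; default pi/3,
#'   i.e. a 120 degree sector).
#' @param overlap cargo-vs-Golgi overlap control in `[0, 1]`: each cargo
#'   punctum is placed inside the Golgi blob with this probability (and
#'   kept clear of it otherwise).  `NULL` keeps the radial mixture.
#' @param background constant background level (counts).
#' @param noise_sigma Gaussian read-noise sd (counts).
#' @param poisson_noise add Poisson shot noise.
#' @param margin empty border around each cell tile (px).
#' @param seed RNG seed.
#' @return `scene_config` list.
#' @export
scene_config <- function(n_cells = 25,
                         cell_radius = c(50, 65),
                         axis_ratio = c(1, 1.4),
                         boundary_wobble = 0.04,
                         nucleus_fraction = 0.35,
                         n_puncta = 20,
                         puncta_amplitude = 200,
                         amplitude_sdlog = 0.35,
                         psf_sigma = 2,
                         p_perinuclear = 0.5,
                         dapi_intensity = 150,
                         golgi_area_px2 = 120,
                         golgi_amplitude = 180,
                         golgi_front_bias = NULL,
                         fa_count = 0,
                         fa_mean_area = 60,
                         fa_area_cv = 0.2,
                         fa_amplitude = 150,
                         fa_front_bias = NULL,
                         fa_polarized_prob = NULL,
                         front_direction = 0,
                         front_half_width = pi / 3,
                         overlap = NULL,
                         background = 10,
                         noise_sigma = 5,
                         poisson_noise = FALSE,
                         margin = 8,
                         seed = 1) {
  cfg <- as.list(environment())
  if (n_cells < 1) trk_stop("bad-config", "n_cells must be >= 1")
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1)
    trk_stop("bad-config", "nucleus_fraction must lie in (0, 1)")
  for (nm in c("p_perinuclear", "golgi_front_bias", "fa_front_bias",
               "fa_polarized_prob", "overlap")) {
    v <- cfg[[nm]]
    if (!is.null(v) && (v < 0 || v > 1))
      trk_stop("bad-config", paste(nm, "must lie in [0, 1]"))
  }
  if (n_puncta < 0 || fa_count < 0) trk_stop("bad-config", "counts must be >= 0")
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d cells, %d puncta (p_perinuclear = %.2f), %d FAs, seed %d\n",
              x$n_cells, x$n_puncta, x$p_perinuclear, x$fa_count, x$seed))
  invisible(x)
}

# radius of a perturbed ellipse boundary at angles th (vectorized)
boundary_radius <- function(th, r0, axis, wob) {
  a <- r0 * sqrt(axis); b <- r0 / sqrt(axis)
  re <- a * b / sqrt((b * cos(th - wob$phase0))^2 + (a * sin(th - wob$phase0))^2)
  re * (1 + wob$w2 * cos(2 * th + wob$ph2) + wob$w3 * cos(3 * th + wob$ph3))
}

# accumulate Gaussian puncta into an image (peak amplitude parameterization)
render_gaussians <- function(img, x, y, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    c0 <- max(1L, floor(x[i] - ext)); c1 <- min(w, ceiling(x[i] + ext))
    r0 <- max(1L, floor(y[i] - ext)); r1 <- min(h, ceiling(y[i] + ext))
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 0.5; ys <- (r0:r1) - 0.5
    g <- amp[i] * outer(exp(-(ys - y[i])^2 / (2 * sigma^2)),
                        exp(-(xs - x[i])^2 / (2 * sigma^2)))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
  }
  img
}

# accumulate hard disks (area-exact structures for particle analysis)
render_disks <- function(img, x, y, radius, amp) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_along(x)) {
    ext <- ceiling(radius[i]) + 1L
    c0 <- max(1L, floor(x[i] - ext)); c1 <- min(w, ceiling(x[i] + ext))
    r0 <- max(1L, floor(y[i] - ext)); r1 <- min(h, ceiling(y[i] + ext))
    xs <- (c0:c1) - 0.5; ys <- (r0:r1) - 0.5
    d2 <- outer((ys - y[i])^2, (xs - x[i])^2, `+`)
    patch <- img[r0:r1, c0:c1]
    patch[d2 <= radius[i]^2] <- patch[d2 <= radius[i]^2] + amp[i]
    img[r0:r1, c0:c1] <- patch
  }
  img
}

apply_noise <- function(img, cfg) {
  img <- img + cfg$background
  if (cfg$poisson_noise) img <- stats::rpois(length(img), pmax(img, 0)) + 0 * img
  if (cfg$noise_sigma > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise_sigma)
  img[img < 0] <- 0
  matrix(img, nrow = nrow(cfg$.blank))
}

#' Simulate a multi-channel scene with ground truth
#'
#' Renders `n_cells` cells, each in its own tile, with channels `cargo`
#' (puncta drawn from the perinuclear/peripheral radial mixture), `dapi`
#' (nucleus fill), `golgi` (blob near the nucleus) and — when
#' `fa_count > 0` — `fa` (edge-localized disks).  Returns the images, the
#' ROIs and a full ground-truth record.
#'
#' @param config a [scene_config()].
#' @return `synthetic_scene`: list with `cells` (per cell: `images` named
#'   list of matrices, `roi`, `truth`), `rois` (named list), `truth`
#'   (per-cell summaries: true puncta classes, FA count/areas, in-sector
#'   fraction, overlap target) and `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  cells <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) cells[[i]] <- simulate_cell(config)
  names(cells) <- sprintf("cell_%03d", seq_len(config$n_cells))
  rois <- lapply(cells, `[[`, "roi")
  truth <- lapply(cells, `[[`, "truth")
  structure(list(cells = cells, rois = rois, truth = truth, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells, channels: %s\n", length(x$cells),
              paste(names(x$cells[[1]]$images), collapse = ", ")))
  invisible(x)
}

simulate_cell <- function(cfg) {
  r0 <- stats::runif(1, cfg$cell_radius[1], cfg$cell_radius[2])
  axis <- stats::runif(1, cfg$axis_ratio[1], cfg$axis_ratio[2])
  wob <- list(phase0 = stats::runif(1, 0, 2 * pi),
              w2 = stats::runif(1, 0, cfg$boundary_wobble),
              w3 = stats::runif(1, 0, cfg$boundary_wobble),
              ph2 = stats::runif(1, 0, 2 * pi), ph3 = stats::runif(1, 0, 2 * pi))
  rmax <- r0 * sqrt(max(cfg$axis_ratio)) * (1 + 2 * cfg$boundary_wobble)
  side <- 2 * ceiling(rmax + cfg$margin)
  ctr <- c(side / 2, side / 2)

  th <- seq(0, 2 * pi, length.out = 73)[-73]
  rc <- boundary_radius(th, r0, axis, wob)
  cell_poly <- cbind(x = ctr[1] + rc * cos(th), y = ctr[2] + rc * sin(th))
  nuc_poly <- cbind(x = ctr[1] + cfg$nucleus_fraction * rc * cos(th),
                    y = ctr[2] + cfg$nucleus_fraction * rc * sin(th))
  roi <- cell_roi(cell_poly, nuc_poly)
  # interpolators for boundary radii at arbitrary angles
  r_at <- function(a) stats::approx(c(th, 2 * pi), c(rc, rc[1]),
                                    xout = a %% (2 * pi))$y
  blank <- matrix(0, side, side)
  cfg$.blank <- blank

  # --- Golgi blob: disk just outside the nucleus ------------------------
  g_bias <- cfg$golgi_front_bias
  g_ang <- if (!is.null(g_bias) && stats::runif(1) < g_bias)
    cfg$front_direction + stats::runif(1, -cfg$front_half_width, cfg$front_half_width)
  else stats::runif(1, 0, 2 * pi)
  g_r <- sqrt(cfg$golgi_area_px2 / pi)
  nr <- cfg$nucleus_fraction * r_at(g_ang)
  g_pos <- ctr + (nr + g_r + 1) * c(cos(g_ang), sin(g_ang))
  golgi <- render_disks(blank, g_pos[1], g_pos[2], g_r, cfg$golgi_amplitude)

  # --- cargo puncta: radial mixture (or Golgi-overlap control) ----------
  n <- cfg$n_puncta
  cls <- character(0); px <- py <- amp <- numeric(0)
  if (n > 0) {
    amp <- stats::rlnorm(n, log(cfg$puncta_amplitude), cfg$amplitude_sdlog)
    if (!is.null(cfg$overlap)) {
      cls <- ifelse(stats::runif(n) < cfg$overlap, "in_marker", "out_marker")
      px <- py <- numeric(n)
      for (j in seq_len(n)) {
        if (cls[j] == "in_marker") {
          rr <- stats::runif(1, 0, max(g_r - 2 * cfg$psf_sigma, 0.5))
          aa <- stats::runif(1, 0, 2 * pi)
          px[j] <- g_pos[1] + rr * cos(aa); py[j] <- g_pos[2] + rr * sin(aa)
        } else {
          repeat {
            aa <- stats::runif(1, 0, 2 * pi)
            rr <- stats::runif(1, cfg$nucleus_fraction + 0.05, 0.95) * r_at(aa)
            cx <- ctr[1] + rr * cos(aa); cy <- ctr[2] + rr * sin(aa)
            if (sqrt(sum((c(cx, cy) - g_pos)^2)) > g_r + 3 * cfg$psf_sigma) break
          }
          px[j] <- cx; py[j] <- cy
        }
      }
    } else {
      cls <- ifelse(stats::runif(n) < cfg$p_perinuclear, "perinuclear", "peripheral")
      aa <- stats::runif(n, 0, 2 * pi)
      cb <- r_at(aa); nb <- cfg$nucleus_fraction * cb
      u <- stats::runif(n)
      d <- ifelse(cls == "perinuclear",
                  nb + (0.03 + 0.17 * u) * (cb - nb),
                  cb - (0.03 + 0.10 * u) * (cb - nb))
      px <- ctr[1] + d * cos(aa); py <- ctr[2] + d * sin(aa)
    }
  }
  cargo <- render_gaussians(blank, px, py, amp, cfg$psf_sigma)

  # --- DAPI: nucleus fill ----------------------------------------------
  dapi <- blank
  nmask <- rasterize_polygon(nuc_poly, side, side)
  dapi[nmask] <- cfg$dapi_intensity

  # --- FA disks on the cell edge ---------------------------------------
  fa_df <- NULL; fa <- NULL; polarized_true <- NA
  if (cfg$fa_count > 0) {
    bias <- cfg$fa_front_bias
    if (!is.null(cfg$fa_polarized_prob)) {
      polarized_true <- stats::runif(1) < cfg$fa_polarized_prob
      bias <- if (polarized_true) 1 else NULL
    }
    areas <- pmax(stats::rnorm(cfg$fa_count, cfg$fa_mean_area,
                               cfg$fa_area_cv * cfg$fa_mean_area), 9)
    radii <- sort(sqrt(areas / pi), decreasing = TRUE)  # big disks pack first
    fx <- fy <- numeric(0); fin <- logical(0); kept_r <- numeric(0)
    for (j in seq_len(cfg$fa_count)) {
      placed <- FALSE
      for (try in 1:1000) {
        aa <- if (!is.null(bias) && stats::runif(1) < bias)
          cfg$front_direction + stats::runif(1, -cfg$front_half_width, cfg$front_half_width)
        else stats::runif(1, 0, 2 * pi)
        cb <- r_at(aa)
        # FAs occupy the lamellipodial margin, a band ~20 px deep; disks
        # keep a >1.5 px gap so rasterized particles never 8-connect
        d <- cb - radii[j] - 1 - stats::runif(1, 0, 24)
        cx <- ctr[1] + d * cos(aa); cy <- ctr[2] + d * sin(aa)
        if (length(fx) == 0 ||
            all(sqrt((fx - cx)^2 + (fy - cy)^2) > radii[j] + kept_r + 1.6)) {
          fx <- c(fx, cx); fy <- c(fy, cy); kept_r <- c(kept_r, radii[j])
          fin <- c(fin, abs(angle_diff(aa, cfg$front_direction)) <= cfg$front_half_width)
          placed <- TRUE
          break
        }
      }
      if (!placed) { # crowded cell: place anyway, truth records it
        fx <- c(fx, cx); fy <- c(fy, cy); kept_r <- c(kept_r, radii[j])
        fin <- c(fin, abs(angle_diff(aa, cfg$front_direction)) <= cfg$front_half_width)
      }
    }
    f_amp <- cfg$fa_amplitude * stats::rlnorm(cfg$fa_count, 0, 0.15)
    fa <- render_disks(blank, fx, fy, kept_r, f_amp)
    fa_df <- data.frame(x = fx, y = fy, radius = kept_r,
                        area_px2 = pi * kept_r^2, amplitude = f_amp,
                        in_sector = fin)
  }

  images <- list(cargo = apply_noise(cargo, cfg),
                 dapi = apply_noise(dapi, cfg),
                 golgi = apply_noise(golgi, cfg))
  if (!is.null(fa)) images$fa <- apply_noise(fa, cfg)

  truth <- list(
    r0 = r0, axis_ratio = axis, side = side, center = ctr,
    puncta = if (n > 0) data.frame(x = px, y = py, class = cls, amplitude = amp)
             else NULL,
    golgi = list(x = g_pos[1], y = g_pos[2], radius = g_r,
                 angle = wrap_angle(g_ang),
                 in_sector = abs(angle_diff(g_ang, cfg$front_direction)) <=
                   cfg$front_half_width),
    fa = fa_df,
    fa_in_sector_fraction = if (!is.null(fa_df))
      sum(fa_df$area_px2[fa_df$in_sector]) / sum(fa_df$area_px2) else NA_real_,
    polarized_true = polarized_true,
    overlap_target = cfg$overlap)
  list(images = images, roi = roi, truth = truth)
}

#' Write a synthetic scene to disk
#'
#' One multi-page 16-bit TIFF per channel (page = cell), the ROIs as JSON
#' and the ground truth as JSON.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- names(scene$cells[[1]]$images)
  paths <- c()
  for (ch in chans) {
    p <- file.path(dir, paste0(ch, ".tif"))
    write_image_tiff(lapply(scene$cells, function(cl) cl$images[[ch]]), p)
    paths[ch] <- p
  }
  paths["rois"] <- file.path(dir, "rois.json")
  write_roi_json(scene$rois, paths[["rois"]])
  paths["truth"] <- file.path(dir, "truth.json")
  tr <- lapply(scene$truth, function(t) {
    t$puncta <- if (!is.null(t$puncta)) as.list(t$puncta)
    t$fa <- if (!is.null(t$fa)) as.list(t$fa)
    t
  })
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Simulate vesicle or cell tracks
#'
#' Directed tracks step `v * dt` along a fixed per-track random direction
#' plus isotropic Gaussian jitter; Brownian tracks take `N(0, sigma^2)`
#' steps per axis.
#'
#' @param n_tracks number of tracks.
#' @param motion `"directed"` or `"brownian"`.
#' @param v directed speed (px per unit time).
#' @param jitter Gaussian jitter sd per axis (directed motion, px).
#' @param sigma Brownian step sd per axis (px).
#' @param n_frames frames per track (>= 2).
#' @param dt frame interval.
#' @param seed RNG seed.
#' @return data.frame `track_id`, `frame`, `t`, `x`, `y` with attribute
#'   `truth` (list: motion, v/jitter or sigma, per-track direction).
#' @export
simulate_tracks <- function(n_tracks, motion = c("directed", "brownian"),
                            v = 0.5, jitter = 0.05, sigma = 0.5,
                            n_frames = 100, dt = 1, seed = 1) {
  motion <- match.arg(motion)
  if (n_frames < 2) trk_stop("bad-config", "n_frames must be >= 2")
  set.seed(seed)
  dirs <- stats::runif(n_tracks, 0, 2 * pi)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    if (motion == "directed") {
      dx <- v * dt * cos(dirs[i]) + stats::rnorm(n_frames - 1, 0, jitter)
      dy <- v * dt * sin(dirs[i]) + stats::rnorm(n_frames - 1, 0, jitter)
    } else {
      dx <- stats::rnorm(n_frames - 1, 0, sigma)
      dy <- stats::rnorm(n_frames - 1, 0, sigma)
    }
    rows[[i]] <- data.frame(track_id = sprintf("track_%04d", i),
                            frame = seq_len(n_frames) - 1L,
                            t = (seq_len(n_frames) - 1L) * dt,
                            x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(motion = motion, v = v, jitter = jitter,
                             sigma = sigma, dt = dt, directions = dirs)
  out
}

#' Simulate an in-cell ELISA plate
#'
#' Well signals are truth times multiplicative log-normal noise with the
#' given CV; a shared per-well cell-number factor (10% CV) multiplies both
#' the cargo signal and the BCA readout, which is what the BCA
#' normalization removes.
#'
#' @param true_uptake true internalized fraction of surface-bound cargo.
#' @param true_recycled true recycled fraction of internalized cargo.
#' @param n_replicates wells per role.
#' @param noise_cv readout noise CV (0 = noise-free).
#' @param time_min nominal chase time recorded in the table.
#' @param condition condition label.
#' @param seed RNG seed.
#' @return data.frame `well`, `condition`, `time_min`, `signal`,
#'   `bca_signal`, `role` with attribute `truth`.
#' @export
simulate_plate <- function(true_uptake, true_recycled = 0.6,
                           n_replicates = 6, noise_cv = 0.05,
                           time_min = 10, condition = "cond_A", seed = 1) {
  if (true_uptake < 0 || true_uptake > 1 || true_recycled < 0 || true_recycled > 1)
    trk_stop("bad-config", "fractions must lie in [0, 1]")
  set.seed(seed)
  s_surface <- 2.0; s_bca <- 1.0      # arbitrary instrument scales
  lnoise <- function(n, cv) if (cv <= 0) rep(1, n) else {
    sdl <- sqrt(log(1 + cv^2)); stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  roles <- c("sample", "surface_total", "strip_control")
  truthval <- c(sample = true_uptake * s_surface,
                surface_total = s_surface,
                strip_control = true_uptake * (1 - true_recycled) * s_surface)
  rows <- list()
  wi <- 0
  for (role in roles) for (r in seq_len(n_replicates)) {
    wi <- wi + 1
    cellf <- lnoise(1, 0.10)          # cell-number variation, shared
    rows[[wi]] <- data.frame(
      well = sprintf("%s%02d", LETTERS[match(role, roles)], r),
      condition = condition, time_min = time_min,
      signal = truthval[[role]] * cellf * lnoise(1, noise_cv),
      bca_signal = s_bca * cellf * lnoise(1, noise_cv),
      role = role)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(uptake = true_uptake, recycled = true_recycled,
                             noise_cv = noise_cv)
  out
}

#' Simulate a densitometric degradation table
#'
#' Band intensities decay exponentially with the given half-life; band and
#' loading control each get multiplicative log-normal noise.
#'
#' @param half_life true half-life (minutes).
#' @param times sampling times (minutes; must include 0).
#' @param noise_cv multiplicative noise CV on band and control.
#' @param seed RNG seed.
#' @return data.frame `time_min`, `band`, `control` with attribute `truth`.
#' @export
simulate_densitometry <- function(half_life = 30, times = seq(0, 120, by = 15),
                                  noise_cv = 0.05, seed = 1) {
  set.seed(seed)
  lnoise <- function(n, cv) if (cv <= 0) rep(1, n) else {
    sdl <- sqrt(log(1 + cv^2)); stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  k <- log(2) / half_life
  band <- 100 * exp(-k * times) * lnoise(length(times), noise_cv)
  control <- 100 * lnoise(length(times), noise_cv)
  out <- data.frame(time_min = times, band = band, control = control)
  attr(out, "truth") <- list(half_life = half_life, noise_cv = noise_cv)
  out
}

#' Simulate an endosomal maturation movie
#'
#' Vesicle puncta at fixed positions whose amplitude ramps linearly from 1x
#' to `ramp`x over the movie (a brightening pH probe); background and
#' read noise as in [simulate_scene()].
#'
#' @param n_frames frames (>= 2).
#' @param ramp final/initial amplitude ratio.
#' @param n_vesicles vesicle count.
#' @param side square frame side (px).
#' @param amplitude initial vesicle peak amplitude.
#' @param psf_sigma PSF sigma (px).
#' @param background,noise_sigma noise model as in [scene_config()].
#' @param seed RNG seed.
#' @return list `frames` (list of matrices), `cell_mask`, `truth`
#'   (positions, ramp).
#' @export
simulate_maturation_movie <- function(n_frames = 10, ramp = 2, n_vesicles = 15,
                                      side = 96, amplitude = 120, psf_sigma = 2,
                                      background = 10, noise_sigma = 3,
                                      seed = 1) {
  if (n_frames < 2) trk_stop("bad-config", "n_frames must be >= 2")
  set.seed(seed)
  ctr <- c(side / 2, side / 2); rad <- side / 2 - 6
  aa <- stats::runif(n_vesicles, 0, 2 * pi)
  rr <- rad * sqrt(stats::runif(n_vesicles, 0.05, 0.9))
  vx <- ctr[1] + rr * cos(aa); vy <- ctr[2] + rr * sin(aa)
  amp0 <- amplitude * stats::rlnorm(n_vesicles, 0, 0.2)
  mask <- rasterize_polygon(circle_polygon(rad, ctr), side, side)
  scale <- seq(1, ramp, length.out = n_frames)
  frames <- lapply(scale, function(s) {
    img <- render_gaussians(matrix(0, side, side), vx, vy, s * amp0, psf_sigma)
    img <- img + background + stats::rnorm(length(img), 0, noise_sigma)
    img[img < 0] <- 0
    img
  })
  list(frames = frames, cell_mask = mask,
       truth = list(x = vx, y = vy, amplitude = amp0, ramp = ramp))
}

#' Simulate cargo/marker frame pairs with controlled overlap
#'
#' For each requested overlap value, cargo puncta are placed inside a fixed
#' marker region with that probability (and away from it otherwise), giving
#' a colocalization time course with known ground truth.
#'
#' @param overlaps numeric vector of target overlap fractions, one per time
#'   point.
#' @param n_puncta cargo puncta per frame.
#' @param side square frame side (px).
#' @param marker_radius marker disk radius (px).
#' @param amplitude cargo punctum amplitude; marker fill is 150.
#' @param psf_sigma PSF sigma.
#' @param background,noise_sigma noise model.
#' @param seed RNG seed.
#' @return list `cargo_frames`, `marker_frames`, `mask`, `truth`.
#' @export
simulate_coloc_frames <- function(overlaps, n_puncta = 30, side = 128,
                                  marker_radius = 20, amplitude = 200,
                                  psf_sigma = 2, background = 10,
                                  noise_sigma = 3, seed = 1) {
  set.seed(seed)
  ctr <- c(side / 2, side / 2); rad <- side / 2 - 6
  m_pos <- ctr + c(0.35 * rad, 0)
  mask <- rasterize_polygon(circle_polygon(rad, ctr), side, side)
  marker <- render_disks(matrix(0, side, side), m_pos[1], m_pos[2],
                         marker_radius, 150)
  noisy <- function(img) {
    img <- img + background + stats::rnorm(length(img), 0, noise_sigma)
    img[img < 0] <- 0
    matrix(img, side, side)
  }
  cargo_frames <- vector("list", length(overlaps))
  marker_frames <- vector("list", length(overlaps))
  min_sep <- 2 * psf_sigma + 2   # puncta stay resolvable: pixel overlap
                                 # then tracks the placement fraction
  for (ti in seq_along(overlaps)) {
    inside <- stats::runif(n_puncta) < overlaps[ti]
    px <- py <- numeric(0)
    for (j in seq_len(n_puncta)) {
      for (try in 1:500) {
        if (inside[j]) {
          rr <- stats::runif(1, 0, marker_radius - 2 * psf_sigma)
          aa <- stats::runif(1, 0, 2 * pi)
          cx <- m_pos[1] + rr * cos(aa); cy <- m_pos[2] + rr * sin(aa)
        } else {
          aa <- stats::runif(1, 0, 2 * pi)
          rr <- rad * sqrt(stats::runif(1, 0.02, 0.92))
          cx <- ctr[1] + rr * cos(aa); cy <- ctr[2] + rr * sin(aa)
          if (sqrt(sum((c(cx, cy) - m_pos)^2)) <= marker_radius + 3 * psf_sigma)
            next
        }
        if (length(px) == 0 || all(sqrt((px - cx)^2 + (py - cy)^2) > min_sep))
          break
      }
      px <- c(px, cx); py <- c(py, cy)
    }
    amp <- amplitude * stats::rlnorm(n_puncta, 0, 0.2)
    cargo_frames[[ti]] <- noisy(render_gaussians(matrix(0, side, side),
                                                 px, py, amp, psf_sigma))
    marker_frames[[ti]] <- noisy(marker)
  }
  list(cargo_frames = cargo_frames, marker_frames = marker_frames,
       mask = mask, truth = list(overlaps = overlaps))
}
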