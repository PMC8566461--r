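test_that("track statistics on canonical tracks", {
  straight <- data.frame(t = 0:9, x = 2 * (0:9), y = 0)
  s <- track_stats(straight)
  expect_equal(s$speed, 2)
  expect_equal(s$directionality, 1)
  expect_equal(s$net_displacement, 18)

  back <- data.frame(t = 0:4, x = c(0, 1, 2, 1, 0), y = 0)
  s2 <- track_stats(back)
  expect_equal(s2$net_displacement, 0)
  expect_equal(s2$directionality, 0)

  still <- data.frame(t = 0:3, x = 0, y = 0)
  s3 <- track_stats(still)
  expect_equal(s3$speed, 0)
  expect_equal(s3$directionality, 0)

  expect_error(track_stats(data.frame(t = 0, x = 0, y = 0)),
               class = "track-too-short")
  expect_error(track_stats(data.frame(t = c(0, 2, 1), x = 0:2, y = 0)),
               class = "bad-timebase")
})

test_that("directionality <= 1 and path >= net on random walks", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    tr <- data.frame(t = seq_len(n), x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    s <- track_stats(tr)
    expect_lte(s$directionality, 1)
    expect_gte(s$path_length, s$net_displacement - 1e-12)
  }
})

test_that("Brownian directionality decreases with track length", {
  set.seed(66)
  mean_dir <- vapply(c(10, 40, 160), function(nf) {
    st <- track_stats_table(simulate_tracks(150, "brownian", sigma = 0.5,
                                            n_frames = nf, seed = nf))
    mean(st$directionality)
  }, 0)
  expect_true(all(diff(mean_dir) < 0))
})

test_that("maturation series: flat movies stay flat, ramps are recovered", {
  mask <- matrix(TRUE, 20, 20)
  img <- matrix(0, 20, 20); img[8:12, 8:12] <- 100
  flat <- maturation_series(list(img, img, img), mask, vesicle_threshold = 50)
  expect_equal(diff(flat$mean_vesicle_intensity), c(0, 0))

  mv <- simulate_maturation_movie(10, ramp = 2, seed = 2)
  ms <- maturation_series(mv$frames, mv$cell_mask, normalization = "fold-over-t0")
  expect_equal(ms$mean_vesicle_intensity[1], 1)
  expect_lt(abs(ms$mean_vesicle_intensity[10] - 2), 0.1)

  # frames with no vesicle signal are flagged missing, not an error
  blank <- matrix(0, 20, 20)
  ms2 <- maturation_series(list(img, blank, img), mask, vesicle_threshold = 50)
  expect_equal(ms2$missing_frames, 2L)
  expect_true(is.na(ms2$mean_vesicle_intensity[2]))
})

test_that("faster generated ramps yield proportionally larger recovered slopes", {
  mv_fast <- simulate_maturation_movie(10, ramp = 3, seed = 8)
  mv_slow <- simulate_maturation_movie(10, ramp = 1.5, seed = 9)
  fold <- function(mv) {
    ms <- maturation_series(mv$frames, mv$cell_mask, normalization = "fold-over-t0")
    (ms$mean_vesicle_intensity[10] - 1) / 9
  }
  ratio <- fold(mv_fast) / fold(mv_slow)
  expect_lt(abs(ratio - (3 - 1) / (1.5 - 1)) / 4, 0.15)
})

test_that("endocytosed percent: BCA normalization and scaling invariance", {
  pl <- simulate_plate(true_uptake = 0.5, noise_cv = 0, seed = 1)
  expect_equal(endocytosis_fraction(pl)$percent_internalized, 50)
  # common positive rescaling of every raw signal changes nothing
  pl2 <- pl; pl2$signal <- pl2$signal * 7.3
  expect_equal(endocytosis_fraction(pl2)$percent_internalized, 50)
  # doubling protein in numerator and reference wells cancels
  pl3 <- pl; pl3$bca_signal <- pl3$bca_signal * 2; pl3$signal <- pl3$signal * 2
  expect_equal(endocytosis_fraction(pl3)$percent_internalized, 50)
})

test_that("recycled fraction identities and clamping", {
  expect_equal(recycled_fraction(100, 40)$fraction, 0.6)
  expect_equal(recycled_fraction(100, 100)$fraction, 0)
  rf <- recycled_fraction(100, 105)  # noise pushed remaining above internalized
  expect_equal(rf$fraction, 0)
  expect_true(rf$clamped)
  expect_error(recycled_fraction(0, 0), class = "zero-internalized")
})

test_that("plate recovery under noise stays near the generated truth", {
  pl <- simulate_plate(true_uptake = 0.3, true_recycled = 0.6,
                       n_replicates = 6, noise_cv = 0.05, seed = 14)
  ef <- endocytosis_fraction(pl)
  expect_lt(abs(ef$percent_internalized - 30), 3)
  rt <- recycled_fraction_table(pl)
  expect_lt(abs(rt$recycled_fraction - 0.6), 0.05)
})

test_that("degradation curves normalize by loading control and fit half-life", {
  dc <- degradation_curve(c(0, 1, 2), c(100, 50, 25), c(10, 10, 10), fit = FALSE)
  expect_equal(dc$normalized_intensity, c(100, 50, 25))
  # control doubling with bands doubling cancels
  dc2 <- degradation_curve(c(0, 1, 2), c(100, 200, 200), c(10, 20, 20), fit = FALSE)
  expect_equal(dc2$normalized_intensity, c(100, 100, 100))
  expect_error(degradation_curve(c(0, 1), c(1, 1), c(1, 0)),
               class = "zero-loading-control")
  expect_error(degradation_curve(c(5, 10), c(1, 1), c(1, 1)),
               class = "bad-timebase")

  d <- simulate_densitometry(half_life = 30, times = seq(0, 120, 15),
                             noise_cv = 0.05, seed = 21)
  dc3 <- degradation_curve(d$time_min, d$band, d$control)
  expect_lt(abs(dc3$fitted_half_life - 30) / 30, 0.10)
})
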