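test_that("particle analysis counts and filters hand-built squares", {
  img <- matrix(0, 30, 30)
  img[3:7, 3:7] <- 100
  img[15:19, 20:24] <- 100
  mask <- matrix(TRUE, 30, 30)
  pt <- segment_puncta(img, mask, threshold_method = "fixed", threshold = 50,
                       min_size = 4)
  expect_equal(attr(pt, "count"), 2)
  expect_equal(attr(pt, "mean_area_px2"), 25)
  expect_equal(sort(pt$area_px2), c(25, 25))
  pt2 <- segment_puncta(img, mask, threshold_method = "fixed", threshold = 50,
                        min_size = 30)
  expect_equal(attr(pt2, "count"), 0)
  expect_equal(nrow(pt2), 0)
})

test_that("diagonally touching blobs are one 8-connected particle", {
  img <- matrix(0, 10, 10)
  img[2:3, 2:3] <- 100
  img[4:5, 4:5] <- 100  # touches the first only at a corner
  pt <- segment_puncta(img, matrix(TRUE, 10, 10), threshold_method = "fixed",
                       threshold = 50, min_size = 1)
  expect_equal(attr(pt, "count"), 1)
  expect_equal(pt$area_px2, 8)
})

test_that("particle centroids and calibrated areas are correct", {
  img <- matrix(0, 20, 20)
  img[5:8, 5:8] <- 60  # 4x4 square, centroid at (6.5, 6)... in (x, y)
  pt <- segment_puncta(img, matrix(TRUE, 20, 20), threshold_method = "fixed",
                       threshold = 30, min_size = 4, pixel_size = 0.2)
  expect_equal(pt$x, mean(c(5:8) - 0.5))
  expect_equal(pt$y, mean(c(5:8) - 0.5))
  expect_equal(pt$area_um2, 16 * 0.04)
  expect_equal(pt$mean_intensity, 60)
})

test_that("mean area times count equals total suprathreshold area after filtering", {
  sc <- simulate_scene(scene_config(n_cells = 4, fa_count = 30, n_puncta = 0,
                                    seed = 33))
  for (cl in sc$cells) {
    pt <- segment_puncta(cl$images$fa, cell_mask_of(cl), min_size = 4)
    expect_equal(attr(pt, "count") * attr(pt, "mean_area_px2"),
                 attr(pt, "total_area_px2"))
  }
})

test_that("particle count recovers the generated FA count and size", {
  sc <- simulate_scene(scene_config(n_cells = 6, fa_count = 40, fa_mean_area = 60,
                                    n_puncta = 0, seed = 13))
  counts <- vapply(sc$cells, function(cl)
    attr(segment_puncta(cl$images$fa, cell_mask_of(cl), min_size = 4), "count"), 0)
  areas <- vapply(sc$cells, function(cl)
    attr(segment_puncta(cl$images$fa, cell_mask_of(cl), min_size = 4),
         "mean_area_px2"), 0)
  expect_lt(abs(mean(counts) - 40) / 40, 0.05)
  expect_lt(abs(mean(areas) - 60) / 60, 0.10)
})

test_that("segment_puncta count is invariant to intensity scaling under Otsu", {
  sc <- simulate_scene(scene_config(n_cells = 2, fa_count = 25, n_puncta = 0,
                                    seed = 17))
  cl <- sc$cells[[1]]
  mask <- cell_mask_of(cl)
  n1 <- attr(segment_puncta(cl$images$fa, mask), "count")
  n2 <- attr(segment_puncta(cl$images$fa * 4, mask), "count")
  expect_equal(n1, n2)
})

test_that("golgi area is additive and unit-calibrated", {
  img <- matrix(0, 30, 30)
  img[3:12, 3:12] <- 200
  mask <- matrix(TRUE, 30, 30)
  expect_equal(golgi_area(img, mask, threshold_method = "fixed",
                          threshold = 100)$area_px2, 100)
  expect_equal(golgi_area(img, mask, threshold_method = "fixed", threshold = 100,
                          pixel_size = 0.2)$area_um2, 4)
  img[20:23, 20:29] <- 200  # second blob of 40 px^2
  expect_equal(golgi_area(img, mask, threshold_method = "fixed",
                          threshold = 100)$area_px2, 140)
})

test_that("polarity scoring: all-in, ring null, and count basis", {
  roi <- disc_roi(50, 15, c(60, 60))
  sec <- front_sector(roi, direction = 0, half_width = pi / 3)
  img <- matrix(0, 120, 120)
  img[55:65, 90:100] <- 100  # blob on the +x side, inside the sector
  mask <- traffickr:::rasterize_polygon(roi$cell_outline, 120, 120)
  ps <- polarity_score(img, sec, cell_mask = mask, threshold_method = "fixed",
                       threshold = 50)
  expect_equal(ps$in_sector_fraction, 1)
  expect_true(ps$polarized)

  # uniform ring: a 120-degree sector holds one third of the intensity
  rho <- pixel_radius(120, 120, c(60, 60))
  ring <- matrix(0, 120, 120); ring[rho > 40 & rho < 48] <- 100
  ps2 <- polarity_score(ring, sec, cell_mask = mask, threshold_method = "fixed",
                        threshold = 50)
  expect_equal(ps2$in_sector_fraction, 1 / 3, tolerance = 0.02)
  expect_false(ps2$polarized)

  pt <- data.frame(id = 1:4, x = c(100, 100, 100, 20), y = c(60, 55, 65, 60),
                   area_px2 = rep(10, 4), area_um2 = rep(10, 4),
                   mean_intensity = rep(1, 4))
  pt <- traffickr:::particle_table(pt, 50, 1, "c1")
  ps3 <- polarity_score(pt, sec, basis = "count")
  expect_equal(ps3$in_sector_fraction, 0.75)
  expect_true(ps3$polarized)

  expect_error(polarity_score(matrix(0, 120, 120), sec, cell_mask = mask,
                              threshold_method = "fixed", threshold = 50),
               class = "no-structures")
})

test_that("percent polarized aggregates and errors on empty input", {
  expect_equal(percent_polarized(c(TRUE, TRUE, FALSE, FALSE))$fraction, 0.5)
  expect_equal(percent_polarized(rep(TRUE, 5))$fraction, 1)
  expect_error(percent_polarized(logical(0)), class = "no-cells")
})

test_that("uniform structures calibrate the polarity null to the sector angle", {
  sc <- simulate_scene(scene_config(n_cells = 40, fa_count = 40, n_puncta = 0,
                                    seed = 29))
  fr <- vapply(sc$cells, function(cl)
    polarity_score(cl$images$fa, front_sector(cl$roi, 0, pi / 3),
                   cell_mask = cell_mask_of(cl))$in_sector_fraction, 0)
  # binomial CI for 40 cells x 40 puncta at p = 1/3
  expect_lt(abs(mean(fr) - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / (40 * 40)) + 0.01)
})

test_that("percent polarized tracks the generative polarization probability", {
  sc <- simulate_scene(scene_config(n_cells = 60, fa_count = 30, n_puncta = 0,
                                    fa_polarized_prob = 0.7, seed = 31))
  pol <- vapply(sc$cells, function(cl)
    polarity_score(cl$images$fa, front_sector(cl$roi, 0, pi / 3),
                   cell_mask = cell_mask_of(cl))$polarized, NA)
  truth <- vapply(sc$truth, function(t) t$polarized_true, NA)
  expect_gt(mean(pol == truth), 0.9)
  expect_gt(mean(pol), 0.55)
  expect_lt(mean(pol), 0.85)
})
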