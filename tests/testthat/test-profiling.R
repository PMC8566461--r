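test_that("linescan profiles are exact on uniform and linear fields", {
  roi <- disc_roi(20, 7, c(25, 25))
  segs <- radial_lines(roi, 3, length = 10)
  p <- linescan_profile(matrix(7, 50, 50), segs, step = 1)
  expect_true(all(p$mean_intensity == 7))
  expect_equal(p$distances[1], 0)
  expect_equal(p$n_lines_averaged, 3)

  # I(x, y) = x sampled along +x from x = 0: bilinear interpolation is exact
  img <- matrix(rep(seq_len(220) - 0.5, each = 220), nrow = 220)
  seg <- structure(list(start = c(0, 50), end = c(10, 50), length = 10,
                        width = 1, angle = pi, truncated = FALSE),
                   class = "sampling_segment")
  p <- linescan_profile(img, list(seg), step = 1)
  expect_equal(p$mean_intensity, 0:10)
})

test_that("profile errors: empty segment list and out-of-bounds segments", {
  expect_error(linescan_profile(matrix(0, 5, 5), list()), class = "no-segments")
  seg <- structure(list(start = c(-5, 2), end = c(3, 2), length = 8,
                        width = 1, angle = 0, truncated = FALSE),
                   class = "sampling_segment")
  expect_error(linescan_profile(matrix(0, 5, 5), list(seg)),
               class = "out-of-bounds")
})

test_that("a perinuclear punctum peaks at its generative radial position", {
  roi <- disc_roi(60, 20, c(70, 70))
  # punctum on the +x ray, 30 px from the center => 30 px inward from PM
  img <- traffickr:::render_gaussians(matrix(0, 140, 140), 100, 70, 200, 2)
  p <- linescan_profile(img, radial_lines(roi, angles = 0), step = 0.5)
  expect_lt(abs(p$distances[which.max(p$mean_intensity)] - 30), 2)
})

test_that("compartment maxima pick out signal and subtract background", {
  roi <- disc_roi(100, 30, c(110, 110))
  m <- build_compartment_masks(roi)
  img <- matrix(0, nrow(m$cell), ncol(m$cell))
  img[110, 150] <- 100  # (x, y) = (149.5, 109.5): radius ~39.5, perinuclear
  sc <- compartment_max(img, m, background = "none")
  expect_equal(sc$perinuclear_max, 100)
  expect_equal(sc$peripheral_max, 0)
  sc2 <- compartment_max(matrix(5, nrow(m$cell), ncol(m$cell)), m, background = "none")
  expect_equal(sc2$perinuclear_max, 5)
  expect_equal(sc2$peripheral_max, 5)
  # constant background is floored at zero
  sc3 <- compartment_max(matrix(5, nrow(m$cell), ncol(m$cell)), m, background = 20)
  expect_equal(sc3$perinuclear_max, 0)
})

test_that("classification rule honors the tie margin", {
  lab <- function(pn, pp) classify_cell(list(perinuclear_max = pn, peripheral_max = pp), 0.1)
  expect_equal(lab(100, 10), "perinuclear")
  expect_equal(lab(10, 100), "peripheral")
  expect_equal(lab(100, 95), "ambiguous")
  expect_equal(lab(0, 0), "ambiguous")
})

test_that("percent perinuclear counts ambiguous cells in the denominator", {
  expect_equal(percent_perinuclear(c("perinuclear", "perinuclear", "perinuclear",
                                     "peripheral"))$fraction, 0.75)
  expect_equal(percent_perinuclear(rep("ambiguous", 5))$fraction, 0)
  expect_error(percent_perinuclear(character(0)), class = "no-cells")
  pe <- percent_perinuclear(c("perinuclear", "peripheral", "perinuclear", "perinuclear"),
                            experiment = c(1, 1, 2, 2))
  expect_equal(pe$per_experiment$fraction, c(0.5, 1))
})

test_that("intensity scaling scales profiles and maxima but not labels", {
  set.seed(11)
  sc <- simulate_scene(scene_config(n_cells = 2, p_perinuclear = 0.8, seed = 11))
  cl <- sc$cells[[1]]
  img <- cl$images$cargo
  masks <- build_compartment_masks(cl$roi, dim = dim(img)[c(2, 1)])
  segs <- radial_lines(cl$roi, 3)
  for (c_scale in c(0.5, 3)) {
    p1 <- linescan_profile(img, segs)
    p2 <- linescan_profile(c_scale * img, segs)
    expect_equal(p2$mean_intensity, c_scale * p1$mean_intensity)
    s1 <- compartment_max(img, masks, background = "none")
    s2 <- compartment_max(c_scale * img, masks, background = "none")
    expect_equal(s2$perinuclear_max, c_scale * s1$perinuclear_max)
    expect_equal(s2$peripheral_max, c_scale * s1$peripheral_max)
    expect_equal(classify_cell(s1), classify_cell(s2))
  }
})

test_that("DAPI profiles peak deeper than cargo in perinuclear-weighted scenes", {
  sc <- simulate_scene(scene_config(n_cells = 8, p_perinuclear = 0.9, seed = 19))
  deeper <- vapply(sc$cells, function(cl) {
    segs <- radial_lines(cl$roi, 3)
    pc <- linescan_profile(cl$images$cargo, segs, channel = "Tfn")
    pd <- linescan_profile(cl$images$dapi, segs, channel = "DAPI")
    pd$distances[which.max(pd$mean_intensity)] >
      pc$distances[which.max(pc$mean_intensity)]
  }, NA)
  expect_gt(mean(deeper), 0.8)
})

test_that("classified perinuclear fraction tracks the generative mixing weight", {
  sc <- simulate_scene(scene_config(n_cells = 40, p_perinuclear = 0.8, seed = 23))
  frac <- percent_perinuclear(scene_labels(sc))$fraction
  expect_gt(frac, 0.65)
  expect_lt(frac, 0.95)
})
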