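test_that("identical channels give m1 = m2 = 1 and disjoint channels give 0", {
  a <- matrix(0, 10, 10); a[2:4, 2:4] <- 100
  r <- manders(a, a, threshold_method = "fixed", thresholds = c(50, 50))
  expect_equal(r$m1, 1); expect_equal(r$m2, 1)
  b <- matrix(0, 10, 10); b[7:9, 7:9] <- 100
  for (mode in c("pixel-count", "intensity-weighted")) {
    r <- manders(a, b, threshold_method = "fixed", thresholds = c(50, 50), mode = mode)
    expect_equal(r$m1, 0); expect_equal(r$m2, 0)
  }
})

test_that("hand-countable overlap: 3 foreground px, 2 marker-positive -> m1 = 2/3", {
  ch1 <- matrix(0, 5, 5); ch1[1, 1:3] <- 10
  ch2 <- matrix(0, 5, 5); ch2[1, 1:2] <- 10
  r <- manders(ch1, ch2, threshold_method = "fixed", thresholds = c(5, 5),
               mode = "pixel-count")
  expect_equal(r$m1, 2 / 3)
  expect_equal(r$m2, 1)
})

test_that("coefficients equal the brute-force pixel loop on random pairs", {
  set.seed(101)
  for (i in 1:20) {
    ch1 <- matrix(runif(32 * 32, 0, 100), 32)
    ch2 <- matrix(runif(32 * 32, 0, 100), 32)
    mask <- matrix(runif(32 * 32) > 0.2, 32)
    for (mode in c("pixel-count", "intensity-weighted")) {
      r <- manders(ch1, ch2, mask, threshold_method = "fixed",
                   thresholds = c(40, 60), mode = mode)
      o <- manders_bruteforce(ch1, ch2, mask, 40, 60, mode)
      expect_identical(r$m1, unname(o["m1"]))
      expect_identical(r$m2, unname(o["m2"]))
    }
  }
})

test_that("swap symmetry m1(A,B) = m2(B,A) holds exactly in both modes", {
  set.seed(7)
  ch1 <- matrix(runif(400, 0, 50), 20)
  ch2 <- matrix(runif(400, 0, 50), 20)
  for (mode in c("pixel-count", "intensity-weighted")) {
    ab <- manders(ch1, ch2, threshold_method = "fixed", thresholds = c(20, 30), mode = mode)
    ba <- manders(ch2, ch1, threshold_method = "fixed", thresholds = c(30, 20), mode = mode)
    expect_identical(ab$m1, ba$m2)
    expect_identical(ab$m2, ba$m1)
  }
})

test_that("intensity-weighted m is invariant to channel scaling with proportional thresholds", {
  set.seed(8)
  ch1 <- matrix(runif(400, 0, 50), 20)
  ch2 <- matrix(runif(400, 0, 50), 20)
  r1 <- manders(ch1, ch2, threshold_method = "fixed", thresholds = c(20, 30),
                mode = "intensity-weighted")
  r2 <- manders(5 * ch1, ch2, threshold_method = "fixed", thresholds = c(100, 30),
                mode = "intensity-weighted")
  expect_equal(r1$m1, r2$m1)
  expect_equal(r1$m2, r2$m2)
})

test_that("a channel with no suprathreshold pixels is flagged, not an error", {
  ch1 <- matrix(1, 5, 5)
  ch2 <- matrix(100, 5, 5)
  r <- manders(ch1, ch2, threshold_method = "fixed", thresholds = c(50, 50))
  expect_true(r$empty_channel[["ch1"]])
  expect_true(is.na(r$m1))
  expect_equal(r$m2, 0)
})

test_that("colocalization time course recovers a generated overlap ramp", {
  fr <- simulate_coloc_frames(c(0.1, 0.4, 0.7), n_puncta = 30, seed = 5)
  tc <- fraction_colocalized_over_time(fr$cargo_frames, fr$marker_frames,
                                       fr$mask, times = c(0, 10, 20),
                                       marker = "GM130",
                                       threshold_method = "fixed",
                                       thresholds = c(50, 50))
  expect_equal(nrow(tc), 3)
  expect_true(all(diff(tc$fraction) > 0))
  expect_true(all(abs(tc$fraction - c(0.1, 0.4, 0.7)) <= 0.1))
})

test_that("degenerate time courses behave: full overlap, none, length mismatch", {
  inside <- matrix(0, 20, 20); inside[8:12, 8:12] <- 100
  marker <- matrix(0, 20, 20); marker[5:15, 5:15] <- 80
  tc <- fraction_colocalized_over_time(list(inside, inside), list(marker, marker),
                                       matrix(TRUE, 20, 20), times = c(0, 10),
                                       threshold_method = "fixed",
                                       thresholds = c(50, 50))
  expect_true(all(tc$fraction == 1))
  outside <- matrix(0, 20, 20); outside[1:3, 17:19] <- 100
  tc0 <- fraction_colocalized_over_time(list(outside), list(marker),
                                        matrix(TRUE, 20, 20), times = 0,
                                        threshold_method = "fixed",
                                        thresholds = c(50, 50))
  expect_equal(tc0$fraction, 0)
  expect_error(
    fraction_colocalized_over_time(list(inside), list(marker, marker),
                                   matrix(TRUE, 20, 20), times = c(0, 10)),
    class = "length-mismatch")
})

test_that("masked Otsu segments a bimodal image like the reference implementation", {
  # on a well-separated mixture any threshold inside the gap maximizes the
  # between-class variance, so compare the induced segmentations
  set.seed(3)
  img <- matrix(c(rnorm(500, 30, 5), rnorm(524, 120, 10)), 32)
  ours <- otsu_threshold(as.vector(img))
  ref <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
  expect_identical(img > ours, img > ref)
})
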