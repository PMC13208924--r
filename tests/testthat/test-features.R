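test_that("masked intensities come out in row-major raster order", {
  px <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)
  roi <- roi_image(px, matrix(TRUE, 2, 2))
  expect_identical(extract_masked_intensities(roi), c(10, 20, 30, 40))
  roi2 <- roi_image(px, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2,
                               byrow = TRUE))
  expect_identical(extract_masked_intensities(roi2), c(30, 40))
  expect_error(roi_image(px, matrix(FALSE, 2, 2)), "at least one")
})

test_that("population skewness follows the uncorrected g1 definition", {
  expect_equal(g1_skewness(c(1, 2, 3)), 0)
  expect_equal(g1_skewness(c(1, 1, 1, 5)), 6 / 3^1.5, tolerance = 1e-12)
  expect_equal(g1_skewness(c(4, 4, 4)), 0)  # zero-variance convention
  expect_error(g1_skewness(c(1, 2)), "at least 3")
})

test_that("percentiles use linear interpolation at rank 1 + q/100*(n-1)", {
  expect_equal(percentile(c(1, 2, 3, 4), 50), 2.5)
  expect_equal(percentile(c(1, 2, 3, 4), 25), 1.75)
  expect_equal(percentile(5, 70), 5)
  expect_error(percentile(1:4, 101), "\\[0, 100\\]")
  expect_error(percentile(1:4, -1), "\\[0, 100\\]")
})

test_that("modal value breaks ties by the smallest intensity", {
  expect_equal(most_frequent_value(c(1, 2, 2, 3)), 2)
  expect_equal(most_frequent_value(c(1, 1, 2, 2)), 1)
  expect_equal(most_frequent_value(7), 7)
  expect_error(most_frequent_value(c(1.5, 1.5)), "integer")
})

test_that("rms and rss follow the quadratic-mean / Euclidean-norm reading", {
  r <- rms_and_rss(c(10, 20, 30, 40))
  expect_equal(r$rms_level, sqrt(750), tolerance = 1e-12)
  expect_equal(r$rss_level, sqrt(3000), tolerance = 1e-12)
  r2 <- rms_and_rss(rep(7, 9))
  expect_equal(r2$rms_level, 7)
  expect_equal(r2$rss_level, 7 * 3)
})

test_that("Katz fractal dimension handles the worked and degenerate cases", {
  expect_equal(katz_fd(c(0, 1, 2, 3)), 1)       # straight line: d = L
  expect_equal(katz_fd(c(3, 3, 3, 3)), 1)       # constant convention
  # zigzag hand example: z-scores +-{-0.8165, 1.2247}, L = 9.0921, d = 4
  zig <- c(0, 1, 0, 1, 0)
  expect_equal(katz_fd(zig), oracle_katz(zig), tolerance = 1e-12)
  expect_equal(katz_fd(zig), 2.4528348, tolerance = 1e-5)
  expect_error(katz_fd(c(1, 2)), "at least 3")
})

test_that("the worked 2x2 full-mask ROI reproduces every hand value", {
  roi <- roi_image(matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE),
                   matrix(TRUE, 2, 2))
  f <- compute_feature_set(roi)
  expect_equal(f$pixel_count, 4L)
  expect_equal(f$mean, 25)
  expect_equal(f$median, 25)
  expect_equal(f$minimum, 10L)
  expect_equal(f$maximum, 40L)
  expect_equal(f$most_frequent_value, 10L)
  expect_equal(f$skewness, 0)
  expect_equal(f$rms_level, sqrt(750), tolerance = 1e-12)
  expect_equal(f$rss_level, sqrt(3000), tolerance = 1e-12)
  expect_equal(f$p10, 13)
  expect_equal(f$p90, 37)
})

test_that("a constant ROI degenerates to its value with zero shape", {
  roi <- roi_image(matrix(5L, 4, 5), matrix(TRUE, 4, 5))
  f <- compute_feature_set(roi)
  expect_equal(f$mean, 5)
  expect_equal(f$median, 5)
  expect_equal(f$most_frequent_value, 5L)
  expect_equal(f$rms_level, 5)
  expect_equal(f$skewness, 0)
  expect_equal(f$katz_fd, 1)
})

test_that("location shifts move location features and leave shape fixed", {
  set.seed(11)
  for (i in 1:20) {
    roi <- random_small_roi()
    k <- sample(1:50, 1)
    shifted <- roi_image(roi$pixels + k, roi$mask)
    f0 <- compute_feature_set(roi)
    f1 <- compute_feature_set(shifted)
    for (col in c("mean", "median", "minimum", "maximum",
                  "most_frequent_value", "p10", "p25", "p75", "p90")) {
      expect_equal(f1[[col]], f0[[col]] + k, tolerance = 1e-12)
    }
    expect_equal(f1$skewness, f0$skewness, tolerance = 1e-9)
    expect_equal(f1$katz_fd, f0$katz_fd, tolerance = 1e-9)
  }
})

test_that("positive scaling leaves skewness and Katz FD unchanged", {
  set.seed(12)
  for (i in 1:20) {
    roi <- random_small_roi()
    scaled <- roi_image(roi$pixels * 3L, roi$mask)
    f0 <- compute_feature_set(roi)
    f1 <- compute_feature_set(scaled)
    expect_equal(f1$skewness, f0$skewness, tolerance = 1e-9)
    expect_equal(f1$katz_fd, f0$katz_fd, tolerance = 1e-9)
  }
})

test_that("order-statistic chain holds on random ROIs", {
  set.seed(13)
  for (i in 1:50) {
    f <- compute_feature_set(random_small_roi())
    expect_true(f$minimum <= f$p10)
    expect_true(f$p10 <= f$p25)
    expect_true(f$p25 <= f$median)
    expect_true(f$median <= f$p75)
    expect_true(f$p75 <= f$p90)
    expect_true(f$p90 <= f$maximum)
  }
})

test_that("smoothing a noise waveform strictly lowers its Katz FD", {
  set.seed(14)
  for (i in 1:10) {
    w <- rnorm(400)
    sm <- as.vector(stats::filter(w, rep(1 / 5, 5), sides = 2))
    sm <- sm[!is.na(sm)]
    expect_true(katz_fd(w) > katz_fd(sm))
    expect_true(katz_fd(w) >= 1)
  }
})
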