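test_that("calibration derives the within-ROI spread from the p10/p90 gap", {
  cfg <- default_generator_config()
  # hand arithmetic: (571.89 - 447.64) / 2.5631 and (501.51 - 380.29) / 2.5631
  expect_equal(cfg$params$bipolar$left$sigma_within, 48.48, tolerance = 1e-4)
  expect_equal(cfg$params$control$left$sigma_within, 47.29, tolerance = 1e-4)
  expect_equal(cfg$params$bipolar$left$mu_subject, 511.19)
  expect_equal(cfg$params$bipolar$left$sigma_subject, 106.96)
  expect_equal(cfg$params$bipolar$left$gamma_within, -0.11)
})

test_that("symmetric percentile input gives k/1.2816 spread and zero shape", {
  rows <- data.frame(group = rep(c("bipolar", "control"), each = 2),
                     side = rep(c("left", "right"), 2),
                     mean = 100, between_sd = 10,
                     p10 = 100 - 20, p90 = 100 + 20,
                     skewness = 0, pixcount_mean = 200, pixcount_sd = 10)
  cfg <- calibrate_config_from_table(rows, n_per_group = 5,
                                     female_counts = c(bipolar = 3,
                                                       control = 2),
                                     age_mean = c(bipolar = 30, control = 30),
                                     age_sd = c(bipolar = 5, control = 5))
  expect_equal(cfg$params$bipolar$left$sigma_within, 20 / qnorm(0.9),
               tolerance = 1e-12)
  expect_equal(sn_params_from_moments(
    100, cfg$params$bipolar$left$sigma_within, 0)$alpha, 0)
})

test_that("calibration rejects inverted percentiles and extreme skewness", {
  rows <- as.data.frame(reference_cohort_summaries())
  bad <- rows; bad$p90[1] <- bad$p10[1] - 1
  expect_error(calibrate_config_from_table(bad), "p90 must exceed p10")
  bad2 <- rows; bad2$skewness[2] <- 0.9953
  expect_error(calibrate_config_from_table(bad2), "skewness")
  expect_error(generator_config(list()), "missing group")
})

test_that("mask generation hits the target count and stays connected", {
  m <- make_roi_mask(948, axes_ratio = 2.2, seed = 1)
  expect_equal(sum(m), 948)          # within the +-5% contract, in fact exact
  expect_true(sum(m) >= 901 && sum(m) <= 995)
  small <- make_roi_mask(16, axes_ratio = 1.0, seed = 2)
  expect_true(abs(sum(small) - 16) <= 1)
  for (s in 1:10) {
    mk <- make_roi_mask(sample(100:1200, 1), seed = s)
    lab <- EBImage::bwlabel(mk * 1)
    expect_equal(max(lab), 1)        # one connected component
  }
})

test_that("mask generation is deterministic and errors on impossible grids", {
  expect_identical(make_roi_mask(500, seed = 9), make_roi_mask(500, seed = 9))
  expect_error(make_roi_mask(500, grid_shape = c(10, 10), seed = 1),
               "10x10")
  expect_error(make_roi_mask(8), ">= 16")
})

test_that("sampled ROIs carry the configured within-ROI distribution", {
  rows <- data.frame(group = rep(c("bipolar", "control"), each = 2),
                     side = rep(c("left", "right"), 2),
                     mean = 500, between_sd = 0.001,
                     p10 = 500 - 48 * qnorm(0.9), p90 = 500 + 48 * qnorm(0.9),
                     skewness = 0, pixcount_mean = 10000, pixcount_sd = 0)
  cfg <- calibrate_config_from_table(rows, n_per_group = 2,
                                     female_counts = c(bipolar = 1,
                                                       control = 1),
                                     age_mean = c(bipolar = 30, control = 30),
                                     age_sd = c(bipolar = 1, control = 1))
  roi <- sample_subject_roi(cfg, "bipolar", "left", seed = 21)
  v <- extract_masked_intensities(roi)
  expect_equal(length(v), 10000)
  # CLT bound: sample mean within 3 * sigma_within / sqrt(n) of the central
  # intensity (central ~ mu to within 0.003 here)
  expect_lt(abs(mean(v) - 500), 3 * 48 / sqrt(10000) + 0.51)
  # symmetric configuration: sample skewness near zero
  expect_lt(abs(g1_skewness(v)), 0.3)
  # quantized and clipped
  expect_true(all(v == round(v)))
  expect_true(all(v >= 0 & v <= 4095))
})

test_that("cohorts realize the configured sizes, sexes and age band", {
  cfg <- default_generator_config()
  cohort <- generate_cohort(cfg, seed = 3)
  expect_length(cohort$subjects, 66)
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  sexes <- vapply(cohort$subjects, `[[`, "", "sex")
  ages <- vapply(cohort$subjects, `[[`, 0, "age")
  expect_equal(sum(groups == "bipolar"), 33)
  expect_equal(sum(sexes == "female" & groups == "bipolar"), 19)
  expect_equal(sum(sexes == "female" & groups == "control"), 18)
  expect_true(all(ages >= 18 & ages <= 65))
  expect_equal(nrow(cohort$manifest), 132)
})

test_that("a 2-per-group smoke cohort yields 4 subjects and 8 ROIs", {
  cfg <- default_generator_config(n_per_group = 2,
                                  female_counts = c(bipolar = 1, control = 1))
  cohort <- generate_cohort(cfg, seed = 5)
  expect_length(cohort$subjects, 4)
  expect_equal(nrow(cohort$manifest), 8)
})

test_that("regenerating with the same seed reproduces every pixel", {
  cfg <- default_generator_config(n_per_group = 3)
  c1 <- generate_cohort(cfg, seed = 8)
  c2 <- generate_cohort(cfg, seed = 8)
  for (id in names(c1$subjects)) {
    expect_identical(c1$subjects[[id]]$roi_left$pixels,
                     c2$subjects[[id]]$roi_left$pixels)
    expect_identical(c1$subjects[[id]]$roi_right$mask,
                     c2$subjects[[id]]$roi_right$mask)
  }
  expect_identical(c1$manifest, c2$manifest)
})

test_that("mean-intensity parameter recovery across a seeded cohort", {
  cfg <- default_generator_config()
  ft <- cohort_feature_table(generate_cohort(cfg, seed = 17))
  for (g in c("bipolar", "control")) for (s in c("left", "right")) {
    p <- cfg$params[[g]][[s]]
    m <- mean(ft$mean[ft$group == g & ft$side == s])
    expect_lt(abs(m - p$mu_subject), 3 * p$sigma_subject / sqrt(33))
  }
})

test_that("waveform smoothing knob lowers the Katz FD, all else equal", {
  cfg <- default_generator_config(n_per_group = 6,
                                  female_counts = c(bipolar = 3, control = 3))
  cfg_smooth <- cfg
  for (s in c("left", "right")) {
    cfg_smooth$params$bipolar[[s]]$smooth_window <- 5L
  }
  f_raw <- cohort_feature_table(generate_cohort(cfg, seed = 31))
  f_sm <- cohort_feature_table(generate_cohort(cfg_smooth, seed = 31))
  expect_lt(mean(f_sm$katz_fd[f_sm$group == "bipolar"]),
            mean(f_raw$katz_fd[f_raw$group == "bipolar"]))
})
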