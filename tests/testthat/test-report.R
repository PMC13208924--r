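test_that("pooled z-scores balance to zero with weights n1, n2", {
  ft <- tiny_feature_table(n_per_group = 5, seed = 21)
  sig <- zscore_signature(ft)
  expect_equal(nrow(sig), 28)
  bal <- sig$n_group1 * sig$z_group1 + sig$n_group2 * sig$z_group2
  expect_equal(max(abs(bal)), 0, tolerance = 1e-9)
})

test_that("equal group means give zero z for both groups", {
  ft <- tiny_feature_table(n_per_group = 4, seed = 22)
  # copy one group's mean-feature values onto the other: equal group means
  for (s in c("left", "right")) {
    a <- ft$group == "bipolar" & ft$side == s
    b <- ft$group == "control" & ft$side == s
    ft$mean[b] <- ft$mean[a]
  }
  sig <- zscore_signature(ft)
  row <- sig[sig$feature == "mean" & sig$side == "left", ]
  expect_equal(row$z_group1, -row$z_group2, tolerance = 1e-9)
  expect_equal(row$z_group1, 0, tolerance = 1e-9)
})

test_that("two point-mass groups standardize symmetrically", {
  ft <- tiny_feature_table(n_per_group = 3, seed = 23)
  a <- ft$group == "bipolar"
  ft$p10[a] <- 90
  ft$p10[!a] <- 110
  sig <- zscore_signature(ft)
  row <- sig[sig$feature == "p10" & sig$side == "left", ]
  s_pool <- sd(ft$p10[ft$side == "left"])
  expect_equal(row$z_group1, (90 - 100) / s_pool, tolerance = 1e-9)
  expect_equal(row$z_group1, -row$z_group2, tolerance = 1e-9)
})

test_that("a constant feature is skipped with a warning", {
  ft <- tiny_feature_table(n_per_group = 3, seed = 24)
  ft$p90 <- 100
  # both sides warn: catch one, tolerate the other
  expect_warning(expect_warning(sig <- zscore_signature(ft),
                                "zero reference SD"))
  expect_false(any(sig$feature == "p90"))
})

test_that("identical groups give a flat percentile-shift series", {
  ft <- tiny_feature_table(n_per_group = 4, seed = 25)
  half <- ft[ft$group == "bipolar", ]
  mirror <- half
  mirror$group <- "control"
  mirror$subject_id <- paste0("m_", mirror$subject_id)
  sh <- percentile_shift_series(rbind(half, mirror))
  expect_equal(max(abs(sh$difference)), 0)
})

test_that("shift series are non-decreasing in percentile level per group", {
  ft <- tiny_feature_table(n_per_group = 6, seed = 26)
  sh <- percentile_shift_series(ft)
  expect_equal(nrow(sh), 10)
  for (s in c("left", "right")) {
    sub <- sh[sh$side == s, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$mean_group1) >= 0))
    expect_true(all(diff(sub$mean_group2) >= 0))
  }
})

test_that("the full pipeline writes every artifact deterministically", {
  cfg <- default_generator_config(n_per_group = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  elapsed <- system.time(run_pipeline(cfg, seed = 1, out_dir = d1))["elapsed"]
  expect_lt(elapsed, 5)
  run_pipeline(cfg, seed = 1, out_dir = d2)
  for (f in c("manifest.csv", "features.csv", "results.csv",
              "signature.csv", "shift.csv", "config.yaml", "run.log")) {
    expect_true(file.exists(file.path(d1, f)))
    r1 <- readLines(file.path(d1, f), warn = FALSE)
    r2 <- readLines(file.path(d2, f), warn = FALSE)
    expect_identical(gsub(d1, "", r1, fixed = TRUE),
                     gsub(d2, "", r2, fixed = TRUE))
  }
  img1 <- sort(list.files(file.path(d1, "images")))
  expect_length(img1, 24)  # 6 subjects x 2 sides x (image + mask)
  for (f in img1) {
    expect_identical(readBin(file.path(d1, "images", f), "raw", 1e6),
                     readBin(file.path(d2, "images", f), "raw", 1e6))
  }
})

test_that("a malformed configuration aborts before any file is written", {
  d <- file.path(withr::local_tempdir(), "run")
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(params = list()), cfg_path)
  expect_error(run_pipeline(cfg_path, seed = 1, out_dir = d))
  expect_false(dir.exists(d))
})

test_that("config files round-trip through YAML", {
  cfg <- default_generator_config()
  p <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, p)
  back <- read_generator_config(p)
  expect_equal(back$params, cfg$params, tolerance = 1e-12)
  expect_equal(back$n_per_group, cfg$n_per_group)
  expect_equal(back$female_counts, cfg$female_counts)
})
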