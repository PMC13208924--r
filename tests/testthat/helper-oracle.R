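# Independent brute-force oracles for the texture features, kept free of
# the package's own code paths: explicit loops, direct moment sums,
# sort-based quantiles, direct polyline arithmetic.

oracle_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  r <- 1 + (q / 100) * (n - 1)
  lo <- floor(r)
  hi <- ceiling(r)
  s[lo] + (r - lo) * (s[hi] - s[lo])
}

oracle_mode_smallest <- function(x) {
  best_val <- NA
  best_count <- -1
  for (v in sort(unique(x))) {
    cnt <- sum(x == v)
    if (cnt > best_count) {
      best_count <- cnt
      best_val <- v
    }
  }
  best_val
}

oracle_skewness <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  if (m2 == 0) 0 else m3 / m2^(3 / 2)
}

oracle_katz <- function(w) {
  n <- length(w)
  mu <- sum(w) / n
  s <- sqrt(sum((w - mu)^2) / n)
  if (s == 0) return(1)
  z <- (w - mu) / s
  L <- 0
  for (i in 2:n) L <- L + sqrt(1 + (z[i] - z[i - 1])^2)
  d <- 0
  for (i in 1:n) d <- max(d, sqrt((i - 1)^2 + (z[i] - z[1])^2))
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

oracle_feature_set <- function(v) {
  ss <- sum(v * v)
  list(pixel_count = length(v),
       mean = sum(v) / length(v),
       median = oracle_quantile(v, 50),
       minimum = min(v),
       maximum = max(v),
       most_frequent_value = oracle_mode_smallest(v),
       skewness = oracle_skewness(v),
       rms_level = sqrt(ss / length(v)),
       rss_level = sqrt(ss),
       p10 = oracle_quantile(v, 10),
       p25 = oracle_quantile(v, 25),
       p75 = oracle_quantile(v, 75),
       p90 = oracle_quantile(v, 90),
       katz_fd = oracle_katz(v))
}

# random small ROI with integer intensities and a random non-trivial mask
random_small_roi <- function() {
  nr <- sample(3:8, 1)
  nc <- sample(3:8, 1)
  mask <- matrix(stats::runif(nr * nc) < 0.7, nr, nc)
  while (sum(mask) < 3) mask <- matrix(stats::runif(nr * nc) < 0.7, nr, nc)
  px <- matrix(sample(0:80, nr * nc, replace = TRUE), nr, nc)
  roi_image(px, mask)
}

# minimal feature table for report tests: one feature column overridden
# with prescribed per-row values, all other columns from a real tiny cohort
tiny_feature_table <- function(n_per_group = 4, seed = 7) {
  cfg <- default_generator_config(n_per_group = n_per_group,
                                  female_counts = c(bipolar = 2, control = 2))
  cohort_feature_table(generate_cohort(cfg, seed = seed))
}
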