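# First-order histogram texture features and the Katz fractal dimension
# for one masked 2D ROI.

#' Names of the texture features, in reporting order
#' @return Character vector of the 14 feature column names.
#' @export
texture_feature_names <- function() {
  c("pixel_count", "mean", "median", "minimum", "maximum",
    "most_frequent_value", "skewness", "rms_level", "rss_level",
    "p10", "p25", "p75", "p90", "katz_fd")
}

#' Extract masked pixel intensities in raster order
#'
#' Returns the intensities of all masked pixels scanned row-major (top row
#' left-to-right first), the order on which the Katz waveform is built.
#'
#' @param roi An ROI as returned by [roi_image()].
#' @return Numeric vector of length equal to the mask pixel count.
#' @export
extract_masked_intensities <- function(roi) {
  stopifnot(inherits(roi, "putatex_roi"))
  if (!any(roi$mask)) stop("ROI mask is empty: no pixels to extract")
  # R matrices are column-major; transpose first to get row-major scan order
  t(roi$pixels)[t(roi$mask)]
}

#' Population (uncorrected Fisher-Pearson) skewness
#'
#' `g1 = m3 / m2^(3/2)` with central moments `m_k = mean((x - mean(x))^k)`.
#' A zero-variance sample returns 0 by convention.
#'
#' @param values Numeric vector, length >= 3.
#' @return Dimensionless skewness.
#' @export
g1_skewness <- function(values) {
  n <- length(values)
  if (n < 3L) stop("skewness needs at least 3 values, got ", n)
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Percentile by linear interpolation
#'
#' The quantile at fractional rank `1 + (q/100) * (n - 1)` over the sorted
#' values (the linear-interpolation convention, `stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile level in \[0, 100\].
#' @return Value in the units of `values`.
#' @export
percentile <- function(values, q) {
  stopifnot(length(values) >= 1L, is.numeric(q), length(q) == 1L)
  if (q < 0 || q > 100) stop("percentile level must lie in [0, 100], got ", q)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Most frequent (modal) integer intensity, ties broken by smallest value
#' @param values Non-empty vector of integer-valued intensities.
#' @return The modal value.
#' @export
most_frequent_value <- function(values) {
  stopifnot(length(values) >= 1L)
  if (any(values != round(values))) {
    stop("most_frequent_value requires integer-quantized intensities")
  }
  u <- sort(unique(values))
  counts <- tabulate(match(values, u))
  u[which.max(counts)]  # which.max returns the first (= smallest) tie
}

#' Root-mean-square and root-sum-of-squares levels
#'
#' `rms = sqrt(sum(x^2) / n)`; `rss = sqrt(sum(x^2))` (the Euclidean norm),
#' so `rss = rms * sqrt(n)` identically.
#'
#' @param values Non-empty numeric vector.
#' @return List with elements `rms_level` and `rss_level`.
#' @export
rms_and_rss <- function(values) {
  stopifnot(length(values) >= 1L)
  ss <- sum(values^2)
  list(rms_level = sqrt(ss / length(values)), rss_level = sqrt(ss))
}

#' Katz fractal dimension of an ordered waveform
#'
#' The waveform is z-score normalized (zero mean, unit population SD;
#' a constant waveform short-circuits to 1), vertices are placed at unit
#' abscissa spacing, and with `L` the total polyline length, `m` the number
#' of segments and `d` the maximum Euclidean distance from the first vertex,
#' `D = log10(m) / (log10(m) + log10(d / L))`. Straight lines give exactly 1.
#'
#' @param waveform Ordered numeric vector, length >= 3.
#' @return Dimensionless fractal dimension, >= 1 for non-degenerate input.
#' @export
katz_fd <- function(waveform) {
  n <- length(waveform)
  if (n < 3L) stop("katz_fd needs at least 3 points, got ", n)
  dev <- waveform - mean(waveform)
  s <- sqrt(mean(dev^2))
  if (s == 0) return(1)
  z <- dev / s
  dz <- diff(z)
  L <- sum(sqrt(1 + dz^2))
  m <- n - 1L
  d <- max(sqrt((seq_len(n) - 1)^2 + (z - z[1L])^2))
  log10(m) / (log10(m) + log10(d / L))
}

#' Compute the full texture feature set for one masked ROI
#'
#' All 14 first-order histogram features plus the Katz fractal dimension,
#' the latter computed on the raster-order waveform from
#' [extract_masked_intensities()].
#'
#' @param roi An ROI as returned by [roi_image()]; at least 3 masked pixels.
#' @return One-row [tibble::tibble] with the columns of
#'   [texture_feature_names()].
#' @examples
#' roi <- roi_image(matrix(c(10, 20, 30, 40), 2, byrow = TRUE),
#'                  matrix(TRUE, 2, 2))
#' compute_feature_set(roi)
#' @export
compute_feature_set <- function(roi) {
  v <- extract_masked_intensities(roi)
  if (length(v) < 3L) {
    stop("feature extraction needs at least 3 masked pixels, got ", length(v))
  }
  power <- rms_and_rss(v)
  tibble::tibble(
    pixel_count = length(v),
    mean = mean(v),
    median = percentile(v, 50),
    minimum = min(v),
    maximum = max(v),
    most_frequent_value = most_frequent_value(v),
    skewness = g1_skewness(v),
    rms_level = power$rms_level,
    rss_level = power$rss_level,
    p10 = percentile(v, 10),
    p25 = percentile(v, 25),
    p75 = percentile(v, 75),
    p90 = percentile(v, 90),
    katz_fd = katz_fd(v)
  )
}
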