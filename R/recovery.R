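# Parameter recovery against the reference cohort summaries.

#' Reference across-subject feature means used as recovery targets
#'
#' The calibration uses only each cell's mean, between-subject SD, p10/p90
#' spread and mean skewness, so the median is a near-replication while the
#' quartiles and the RMS level are out-of-sample predictions of the
#' within-ROI model.
#'
#' @return Tibble: `feature`, `side`, `group`, `reference` (across-subject
#'   mean), `reference_sd` (between-subject SD of that feature).
#' @export
reference_recovery_targets <- function() {
  tibble::tribble(
    ~feature,    ~side,   ~group,    ~reference, ~reference_sd,
    "mean",      "left",  "bipolar", 511.19,     106.96,
    "mean",      "left",  "control", 440.68,     102.21,
    "median",    "left",  "bipolar", 511.92,     106.71,
    "p25",       "left",  "bipolar", 477.92,      97.50,
    "p75",       "left",  "bipolar", 545.70,     117.31,
    "rms_level", "left",  "bipolar", 513.58,     107.82,
    "skewness",  "left",  "bipolar", -0.11,        0.23,
    "skewness",  "left",  "control",  0.11,        0.39,
    "mean",      "right", "bipolar", 476.33,     102.04,
    "mean",      "right", "control", 417.19,      98.46
  )
}

#' Recover the reference feature means from a synthetic cohort
#'
#' For every target of [reference_recovery_targets()], averages the
#' per-subject feature over the matching group x side of the supplied
#' feature table and reports the sampling tolerance
#' `3 * reference_sd / sqrt(n)`.
#'
#' @param features FeatureTable tibble (e.g. from [cohort_feature_table()]).
#' @return The targets tibble extended with `n`, `recovered`, `tolerance`
#'   and `within` (logical: |recovered - reference| <= tolerance).
#' @examples
#' ft <- cohort_feature_table(generate_cohort(default_generator_config(),
#'                                            seed = 1))
#' parameter_recovery_summary(ft)
#' @export
parameter_recovery_summary <- function(features) {
  features <- validate_feature_table(features)
  targets <- reference_recovery_targets()
  targets$n <- NA_integer_
  targets$recovered <- NA_real_
  for (i in seq_len(nrow(targets))) {
    sel <- features$group == targets$group[i] &
      features$side == targets$side[i]
    targets$n[i] <- sum(sel)
    targets$recovered[i] <- mean(features[[targets$feature[i]]][sel])
  }
  targets$tolerance <- 3 * targets$reference_sd / sqrt(targets$n)
  targets$within <- abs(targets$recovered - targets$reference) <=
    targets$tolerance
  targets
}
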