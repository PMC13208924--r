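# Distribution-gated two-group comparisons and the results table.
#
# Gate: both groups must pass Shapiro-Wilk at p > 0.05 for Student's
# (pooled-variance) t; otherwise Mann-Whitney U (normal approximation with
# tie correction, two-sided). Categoricals: chi-square without continuity
# correction when every expected count exceeds 5, else Fisher's exact test.

#' Assess normality of one sample
#'
#' Reports sample skewness, excess kurtosis and the Shapiro-Wilk test; the
#' downstream test selection gates on the Shapiro-Wilk p-value alone.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List of class `putatex_normality` with `n`, `skewness`,
#'   `excess_kurtosis`, `W`, `p`.
#' @export
assess_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("normality assessment needs 3 <= n <= 5000, got ", n)
  }
  if (max(values) == min(values)) {
    stop("degenerate sample: all ", n, " values are identical")
  }
  d <- values - mean(values)
  m2 <- mean(d^2)
  sw <- stats::shapiro.test(values)
  structure(list(n = n,
                 skewness = mean(d^3) / m2^1.5,
                 excess_kurtosis = mean(d^4) / m2^2 - 3,
                 W = unname(sw$statistic),
                 p = sw$p.value),
            class = "putatex_normality")
}

#' Select the two-sample test from two normality reports
#'
#' @param report_a,report_b Reports from [assess_normality()].
#' @return `"t"` when both Shapiro-Wilk p-values exceed 0.05, else `"mwu"`.
#' @export
select_test <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "putatex_normality"),
            inherits(report_b, "putatex_normality"))
  if (report_a$p > 0.05 && report_b$p > 0.05) "t" else "mwu"
}

#' Compare one continuous feature between two groups
#'
#' Runs the test chosen by [select_test()]: Student's two-sample t with
#' pooled variance (or Welch with `welch = TRUE`), or the two-sided
#' Mann-Whitney U with normal approximation and tie correction. Both
#' groups' mean and SD are reported regardless of the test used.
#'
#' @param values_a,values_b Numeric vectors, each n >= 3, non-constant.
#' @param welch Use Welch's unequal-variance t instead of the pooled t.
#' @return One-row tibble: `group1_mean/sd`, `group2_mean/sd`, `test_used`,
#'   `statistic`, `p_value`.
#' @export
compare_feature <- function(values_a, values_b, welch = FALSE) {
  if (max(values_a) == min(values_a) || max(values_b) == min(values_b)) {
    stop("degenerate group: constant sample")
  }
  test <- select_test(assess_normality(values_a), assess_normality(values_b))
  if (test == "t") {
    ht <- stats::t.test(values_a, values_b, var.equal = !welch,
                        alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                             correct = FALSE, alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(group1_mean = mean(values_a),
                 group1_sd = stats::sd(values_a),
                 group2_mean = mean(values_b),
                 group2_sd = stats::sd(values_b),
                 test_used = test, statistic = statistic, p_value = p)
}

#' Compare a 2x2 categorical table between two groups
#'
#' Chi-square without continuity correction when every expected count
#' exceeds 5, otherwise Fisher's exact test (two-sided).
#'
#' @param counts 2x2 matrix of non-negative integer counts
#'   (rows = categories, columns = groups).
#' @return One-row tibble: `test_used` (`"chi2"`/`"fisher"`), `statistic`
#'   (chi-square statistic, NA for Fisher), `p_value`.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected > 5)) {
    ht <- stats::chisq.test(counts, correct = FALSE)
    tibble::tibble(test_used = "chi2", statistic = unname(ht$statistic),
                   p_value = ht$p.value)
  } else {
    ht <- stats::fisher.test(counts, alternative = "two.sided")
    tibble::tibble(test_used = "fisher", statistic = NA_real_,
                   p_value = ht$p.value)
  }
}

#' Build the full two-group results table
#'
#' One comparison row per texture feature x side (14 x 2 = 28) preceded by
#' the gender and age demographic rows, in the reference reporting order.
#' Group 1 is `bipolar`, group 2 `control`. No multiplicity correction is
#' applied by default; `correction = "bh"` adds a Benjamini-Hochberg
#' adjusted column `p_adjusted` over the 28 feature rows.
#'
#' @param features FeatureTable tibble (see [cohort_feature_table()]); must
#'   contain both groups, complete cases only.
#' @param alpha Two-sided significance level used for the `significant`
#'   flag (default 0.05).
#' @param correction `"none"` (default) or `"bh"`.
#' @param welch Passed to [compare_feature()].
#' @return Tibble with 30 rows: `variable`, `side`, group summaries,
#'   `test_used`, `statistic`, `p_value`, `significant` (and `p_adjusted`
#'   with `correction = "bh"`).
#' @export
build_results_table <- function(features, alpha = 0.05,
                                correction = c("none", "bh"),
                                welch = FALSE) {
  correction <- match.arg(correction)
  features <- validate_feature_table(features)
  groups <- sort(unique(features$group))
  if (length(groups) != 2L) {
    stop("results table needs exactly two groups, got: ",
         paste(groups, collapse = ", "))
  }
  g1 <- if ("bipolar" %in% groups) "bipolar" else groups[1]
  g2 <- setdiff(groups, g1)[1]

  subjects <- features[!duplicated(features$subject_id),
                       c("subject_id", "group", "sex", "age")]
  # gender row: counts of female/male per group
  tab <- table(factor(subjects$sex, levels = c("female", "male")),
               factor(subjects$group, levels = c(g1, g2)))
  cat_row <- compare_categorical(unclass(tab)[, , drop = FALSE])
  gender <- tibble::tibble(
    variable = "gender_female", side = NA_character_,
    group1_mean = unname(tab["female", g1]), group1_sd = NA_real_,
    group2_mean = unname(tab["female", g2]), group2_sd = NA_real_,
    test_used = cat_row$test_used, statistic = cat_row$statistic,
    p_value = cat_row$p_value)

  age <- cbind(tibble::tibble(variable = "age", side = NA_character_),
               compare_feature(subjects$age[subjects$group == g1],
                               subjects$age[subjects$group == g2],
                               welch = welch))

  feat_rows <- list()
  for (sd_ in c("left", "right")) {
    for (f in texture_feature_names()) {
      va <- features[[f]][features$group == g1 & features$side == sd_]
      vb <- features[[f]][features$group == g2 & features$side == sd_]
      feat_rows[[paste(sd_, f)]] <- cbind(
        tibble::tibble(variable = f, side = sd_),
        compare_feature(va, vb, welch = welch))
    }
  }
  out <- tibble::as_tibble(rbind(gender, age, do.call(rbind, feat_rows)))
  rownames(out) <- NULL
  if (correction == "bh") {
    out$p_adjusted <- NA_real_
    idx <- !out$variable %in% c("gender_female", "age")
    out$p_adjusted[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  }
  out$significant <- out$p_value < alpha
  attr(out, "groups") <- c(group1 = g1, group2 = g2)
  out
}
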