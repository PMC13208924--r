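# Synthetic cohort generator: seeded two-group cohorts of putamen-like 2D
# ROIs whose per-subject feature summaries reproduce the reference
# case-control statistics the simulator is calibrated to.

GROUPS <- c("bipolar", "control")
SIDES <- c("left", "right")

#' Construct a single-putamen ROI image
#'
#' @param pixels 2D matrix of non-negative integer intensities (signal
#'   units; background pixels may be 0).
#' @param mask Logical matrix of the same shape with at least one TRUE cell.
#' @param side `"left"` or `"right"`.
#' @param pixel_spacing In-plane pixel spacing in mm (informational only).
#' @return An object of class `putatex_roi`.
#' @export
roi_image <- function(pixels, mask, side = "left", pixel_spacing = 0.9) {
  pixels <- as.matrix(pixels)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(pixels), dim(mask))) {
    stop("pixel grid is ", paste(dim(pixels), collapse = "x"),
         " but mask is ", paste(dim(mask), collapse = "x"))
  }
  if (!any(mask)) stop("mask must contain at least one TRUE cell")
  if (any(pixels < 0) || any(pixels != round(pixels))) {
    stop("pixel intensities must be non-negative integers")
  }
  side <- match.arg(side, SIDES)
  structure(list(pixels = pixels, mask = mask, side = side,
                 pixel_spacing = pixel_spacing),
            class = "putatex_roi")
}

#' @export
print.putatex_roi <- function(x, ...) {
  cat("<putatex_roi> ", x$side, " | grid ",
      paste(dim(x$pixels), collapse = "x"),
      " | ", sum(x$mask), " masked pixels\n", sep = "")
  invisible(x)
}

#' Reference cohort summary statistics used for calibration
#'
#' Group-level putamen summaries (across-subject mean, between-subject SD,
#' mean 10th/90th percentile features, mean within-ROI skewness, ROI pixel
#' counts) for 33 bipolar-disorder patients and 33 matched controls on
#' axial T2-FSE imaging. These are the targets the default generator
#' configuration is calibrated to.
#'
#' @return Tibble with one row per group x side.
#' @export
reference_cohort_summaries <- function() {
  tibble::tribble(
    ~group,    ~side,   ~mean,  ~between_sd, ~p10,   ~p90,   ~skewness, ~pixcount_mean, ~pixcount_sd,
    "bipolar", "left",  511.19, 106.96,      447.64, 571.89, -0.11,     948.12,         186.43,
    "control", "left",  440.68, 102.21,      380.29, 501.51,  0.11,     790.48,         287.85,
    "bipolar", "right", 476.33, 102.04,      423.84, 529.50, -0.09,     1083.97,        204.21,
    "control", "right", 417.19,  98.46,      362.74, 472.50, -0.05,     800.06,         253.24
  )
}

#' Reference cohort demographics
#' @return List with per-group female counts and age mean/SD (years).
#' @export
reference_demographics <- function() {
  list(n_per_group = 33L,
       female_counts = c(bipolar = 19L, control = 18L),
       age_mean = c(bipolar = 36.42, control = 37.42),
       age_sd = c(bipolar = 12.69, control = 13.64))
}

validate_group_params <- function(p, label) {
  needed <- c("mu_subject", "sigma_subject", "sigma_within", "gamma_within",
              "pixcount_mean", "pixcount_sd")
  missing <- setdiff(needed, names(p))
  if (length(missing)) {
    stop(label, ": missing generator parameter(s) ",
         paste(missing, collapse = ", "))
  }
  if (p$sigma_subject <= 0) stop(label, ": sigma_subject must be > 0")
  if (p$sigma_within <= 0) stop(label, ": sigma_within must be > 0")
  if (p$pixcount_mean <= 0) stop(label, ": pixcount_mean must be > 0")
  if (p$pixcount_sd < 0) stop(label, ": pixcount_sd must be >= 0")
  if (abs(p$gamma_within) >= sn_max_skewness()) {
    stop(label, ": |gamma_within| must be < ",
         format(sn_max_skewness(), digits = 6))
  }
  if (is.null(p$smooth_window)) p$smooth_window <- 1L
  p$smooth_window <- as.integer(p$smooth_window)
  if (p$smooth_window < 1L || p$smooth_window %% 2L == 0L) {
    stop(label, ": smooth_window must be an odd integer >= 1")
  }
  p
}

#' Construct and validate a generator configuration
#'
#' @param params Nested list `params[[group]][[side]]` for the groups
#'   `"bipolar"`, `"control"` and sides `"left"`, `"right"`, each holding
#'   `mu_subject` (mean per-subject central intensity, signal units),
#'   `sigma_subject` (between-subject SD), `sigma_within` (within-ROI pixel
#'   SD), `gamma_within` (within-ROI population skewness), `pixcount_mean`,
#'   `pixcount_sd` (ROI pixel-count distribution) and optionally
#'   `smooth_window` (odd moving-average window on the raster waveform;
#'   1 = spatially independent pixels, the default).
#' @param n_per_group Subjects per group (>= 2).
#' @param female_counts Named integer vector (`bipolar`, `control`),
#'   each <= `n_per_group`.
#' @param age_mean,age_sd Named numeric vectors per group (years); ages are
#'   clipped to the 18-65 inclusion band.
#' @param intensity_quantization Upper bound of the integer intensity range
#'   (default 4095, i.e. 12-bit storage).
#' @param axes_ratio Ellipse elongation of the ROI mask (putamen-like 2.2).
#' @param roughness Relative amplitude of the low-frequency radial boundary
#'   perturbation of the mask.
#' @return An object of class `putatex_config`.
#' @export
generator_config <- function(params,
                             n_per_group = 33L,
                             female_counts = c(bipolar = 19L, control = 18L),
                             age_mean = c(bipolar = 36.42, control = 37.42),
                             age_sd = c(bipolar = 12.69, control = 13.64),
                             intensity_quantization = 4095L,
                             axes_ratio = 2.2,
                             roughness = 0.08) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L) {
    stop("n_per_group must be an integer >= 2")
  }
  for (g in GROUPS) {
    if (is.null(params[[g]])) stop("params missing group '", g, "'")
    for (s in SIDES) {
      if (is.null(params[[g]][[s]])) {
        stop("params missing side '", s, "' for group '", g, "'")
      }
      params[[g]][[s]] <- validate_group_params(params[[g]][[s]],
                                                paste(g, s, sep = "/"))
    }
    if (is.null(female_counts[[g]])) stop("female_counts missing '", g, "'")
    if (female_counts[[g]] < 0 || female_counts[[g]] > n_per_group) {
      stop("female_counts['", g, "'] must lie in [0, n_per_group]")
    }
    if (is.null(age_mean[[g]]) || is.null(age_sd[[g]])) {
      stop("age_mean/age_sd missing group '", g, "'")
    }
  }
  if (intensity_quantization < 1) stop("intensity_quantization must be >= 1")
  structure(list(params = params,
                 n_per_group = n_per_group,
                 female_counts = vapply(GROUPS, function(g)
                   as.integer(female_counts[[g]]), integer(1)),
                 age_mean = vapply(GROUPS, function(g)
                   as.numeric(age_mean[[g]]), numeric(1)),
                 age_sd = vapply(GROUPS, function(g)
                   as.numeric(age_sd[[g]]), numeric(1)),
                 intensity_quantization = as.integer(intensity_quantization),
                 axes_ratio = axes_ratio,
                 roughness = roughness),
            class = "putatex_config")
}

#' @export
print.putatex_config <- function(x, ...) {
  cat("<putatex_config> ", x$n_per_group, " subjects/group, quantization 0-",
      x$intensity_quantization, "\n", sep = "")
  for (g in GROUPS) for (s in SIDES) {
    p <- x$params[[g]][[s]]
    cat(sprintf("  %-7s %-5s mu %7.2f  sd_subj %6.2f  sd_within %5.2f  skew %+5.2f  px %6.1f+/-%5.1f\n",
                g, s, p$mu_subject, p$sigma_subject, p$sigma_within,
                p$gamma_within, p$pixcount_mean, p$pixcount_sd))
  }
  invisible(x)
}

#' Calibrate a generator configuration from group-level summary rows
#'
#' For each group x side row the per-subject central-intensity distribution
#' is set to `Normal(mean, between_sd)`; the within-ROI pixel SD is derived
#' from the 10th/90th-percentile spread alone,
#' `sigma_within = (p90 - p10) / (2 * qnorm(0.9))`, so quartiles and RMS
#' remain out-of-sample predictions; the within-ROI skew-normal shape is
#' solved from the printed mean skewness; ROI pixel counts follow
#' `Normal(pixcount_mean, pixcount_sd)` rounded and floored at 16.
#'
#' @param rows Data frame with columns `group`, `side`, `mean`,
#'   `between_sd`, `p10`, `p90`, `skewness`, `pixcount_mean`, `pixcount_sd`;
#'   one row for each of the four group x side cells.
#' @param ... Cohort-level settings passed to [generator_config()].
#' @return A validated `putatex_config`.
#' @examples
#' cfg <- calibrate_config_from_table(reference_cohort_summaries())
#' cfg$params$bipolar$left$sigma_within  # 48.48 from the p10/p90 spread
#' @export
calibrate_config_from_table <- function(rows, ...) {
  rows <- as.data.frame(rows)
  needed <- c("group", "side", "mean", "between_sd", "p10", "p90",
              "skewness", "pixcount_mean", "pixcount_sd")
  missing <- setdiff(needed, names(rows))
  if (length(missing)) {
    stop("summary rows missing column(s): ", paste(missing, collapse = ", "))
  }
  params <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lab <- paste(r$group, r$side, sep = "/")
    if (r$p90 <= r$p10) stop(lab, ": p90 must exceed p10")
    if (r$between_sd <= 0) stop(lab, ": between_sd must be > 0")
    if (abs(r$skewness) >= sn_max_skewness()) {
      stop(lab, ": |skewness| must be < ",
           format(sn_max_skewness(), digits = 6))
    }
    params[[r$group]][[r$side]] <- list(
      mu_subject = r$mean,
      sigma_subject = r$between_sd,
      sigma_within = (r$p90 - r$p10) / (2 * stats::qnorm(0.9)),
      gamma_within = r$skewness,
      pixcount_mean = r$pixcount_mean,
      pixcount_sd = r$pixcount_sd
    )
  }
  generator_config(params, ...)
}

#' Default configuration calibrated to the reference cohort
#' @param ... Overrides passed to [generator_config()] via
#'   [calibrate_config_from_table()].
#' @return A `putatex_config`.
#' @export
default_generator_config <- function(...) {
  demo <- reference_demographics()
  args <- utils::modifyList(
    list(rows = reference_cohort_summaries(),
         n_per_group = demo$n_per_group,
         female_counts = demo$female_counts,
         age_mean = demo$age_mean,
         age_sd = demo$age_sd),
    list(...))
  if (!is.null(list(...)$n_per_group) && is.null(list(...)$female_counts)) {
    # keep the reference sex ratio when the cohort is scaled
    args$female_counts <- round(demo$female_counts * args$n_per_group /
                                  demo$n_per_group)
  }
  do.call(calibrate_config_from_table, args)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a putamen-like ROI mask
#'
#' An ellipse (elongation `axes_ratio`) with a low-frequency radial boundary
#' perturbation, rasterized so the realized pixel count equals the target
#' exactly: every grid cell gets a perturbed normalized elliptic radius and
#' the mask keeps the `target_pixcount` smallest radii, a threshold on a
#' star-shaped field, so the component stays connected.
#'
#' @param target_pixcount Target mask size in pixels (>= 16).
#' @param axes_ratio Major/minor semi-axis ratio (>= 1).
#' @param roughness Relative amplitude of the boundary perturbation
#'   (harmonics 2 and 3 with random phases), in \[0, 0.2\].
#' @param grid_shape Optional `c(nrow, ncol)`; defaults to a grid that fits
#'   the perturbed ellipse. An explicit grid too small for the target is an
#'   error naming the grid size.
#' @param seed Optional integer; when given, the mask is drawn from a local
#'   RNG stream and the caller's stream is left untouched.
#' @return Logical matrix with exactly `target_pixcount` TRUE cells.
#' @export
make_roi_mask <- function(target_pixcount, axes_ratio = 2.2,
                          roughness = 0.08, grid_shape = NULL, seed = NULL) {
  target_pixcount <- as.integer(target_pixcount)
  if (is.na(target_pixcount) || target_pixcount < 16L) {
    stop("target_pixcount must be an integer >= 16")
  }
  stopifnot(axes_ratio >= 1, roughness >= 0, roughness <= 0.2)
  with_seed(seed, {
    # semi-axes sized so the unperturbed ellipse area matches the target
    a <- sqrt(target_pixcount * axes_ratio / pi)
    b <- a / axes_ratio
    if (is.null(grid_shape)) {
      grid_shape <- c(2L * ceiling(b * (1 + roughness) * 1.25) + 3L,
                      2L * ceiling(a * (1 + roughness) * 1.25) + 3L)
    }
    nr <- grid_shape[1]; nc <- grid_shape[2]
    if (nr * nc < target_pixcount) {
      stop("grid ", nr, "x", nc, " (", nr * nc, " cells) cannot hold ",
           target_pixcount, " mask pixels")
    }
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    amp <- roughness * stats::runif(2L, 0.5, 1)
    phase <- stats::runif(2L, 0, 2 * pi)
    dy <- matrix(seq_len(nr) - cy, nr, nc)
    dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
    theta <- atan2(dy / b, dx / a)
    boundary <- 1 + amp[1] * cos(2 * theta + phase[1]) +
      amp[2] * cos(3 * theta + phase[2])
    rho <- sqrt((dx / a)^2 + (dy / b)^2) / boundary
    cutoff <- sort(as.vector(rho), partial = target_pixcount)[target_pixcount]
    mask <- rho <= cutoff
    # resolve radius ties (can only overshoot) deterministically
    if (sum(mask) > target_pixcount) {
      extra <- sum(mask) - target_pixcount
      tied <- which(mask & rho == cutoff)
      mask[tied[seq_len(extra)]] <- FALSE
    }
    mask
  })
}

moving_average_odd <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  as.vector(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1L):(half + n)]
}

#' Sample one subject's ROI image for a group and side
#'
#' Draws the subject's central intensity from
#' `Normal(mu_subject, sigma_subject)`, then fills the masked pixels with
#' i.i.d. skew-normal draws whose population mean, SD and skewness equal the
#' central intensity, `sigma_within` and `gamma_within`. With
#' `smooth_window > 1` the raster-order waveform is moving-average smoothed
#' and restandardized to the same mean/SD (injects spatial correlation,
#' lowering the Katz fractal dimension). Values are rounded to integers and
#' clipped to the quantization range.
#'
#' @param config A `putatex_config`.
#' @param group `"bipolar"` or `"control"`.
#' @param side `"left"` or `"right"`.
#' @param seed Optional integer for a local RNG stream.
#' @return A `putatex_roi`.
#' @export
sample_subject_roi <- function(config, group, side, seed = NULL) {
  stopifnot(inherits(config, "putatex_config"))
  group <- match.arg(group, GROUPS)
  side <- match.arg(side, SIDES)
  p <- config$params[[group]][[side]]
  with_seed(seed, {
    npix <- max(16L, as.integer(round(
      stats::rnorm(1, p$pixcount_mean, p$pixcount_sd))))
    mask <- make_roi_mask(npix, axes_ratio = config$axes_ratio,
                          roughness = config$roughness)
    central <- stats::rnorm(1, p$mu_subject, p$sigma_subject)
    vals <- rskewnorm(npix, mean = central, sd = p$sigma_within,
                      gamma = p$gamma_within)
    w <- if (is.null(p$smooth_window)) 1L else p$smooth_window
    if (w > 1L) {
      sm <- moving_average_odd(vals, w)
      s <- stats::sd(sm)
      if (s > 0) vals <- central + (sm - mean(sm)) * p$sigma_within / s
    }
    q <- pmin(pmax(round(vals), 0), config$intensity_quantization)
    pixels <- matrix(0L, nrow(mask), ncol(mask))
    # fill masked cells in row-major raster order with the sampled sequence
    tp <- t(pixels)
    tp[t(mask)] <- as.integer(q)
    roi_image(t(tp), mask, side = side)
  })
}

#' Generate a full seeded two-group cohort
#'
#' `n_per_group` subjects per group with exactly the configured sex counts,
#' ages drawn from the configured normal and clipped to the 18-65 inclusion
#' band, and left and right ROIs sampled per [sample_subject_roi()]. Fully
#' reproducible from the seed.
#'
#' @param config A `putatex_config`.
#' @param seed Integer RNG seed for the whole cohort.
#' @return An object of class `putatex_cohort`: list with `subjects` (list
#'   of records holding `subject_id`, `group`, `sex`, `age`, `roi_left`,
#'   `roi_right`), `manifest` (tibble, one row per subject x side; paths
#'   filled when written to disk), `config` and `seed`.
#' @examples
#' cfg <- default_generator_config(n_per_group = 3)
#' cohort <- generate_cohort(cfg, seed = 1)
#' cohort$manifest
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "putatex_config"))
  subjects <- with_seed(seed, {
    out <- list()
    for (g in GROUPS) {
      n <- config$n_per_group
      nf <- config$female_counts[[g]]
      sexes <- c(rep("female", nf), rep("male", n - nf))
      ages <- pmin(pmax(stats::rnorm(n, config$age_mean[[g]],
                                     config$age_sd[[g]]), 18), 65)
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", substr(g, 1, 3), i)
        out[[id]] <- list(
          subject_id = id, group = g, sex = sexes[i], age = ages[i],
          roi_left = sample_subject_roi(config, g, "left"),
          roi_right = sample_subject_roi(config, g, "right"))
      }
    }
    out
  })
  manifest <- do.call(rbind, lapply(subjects, function(s) {
    tibble::tibble(subject_id = s$subject_id, group = s$group, sex = s$sex,
                   age = s$age, side = SIDES,
                   image_path = NA_character_, mask_path = NA_character_)
  }))
  rownames(manifest) <- NULL
  structure(list(subjects = subjects, manifest = manifest,
                 config = config, seed = as.integer(seed)),
            class = "putatex_cohort")
}

#' @export
print.putatex_cohort <- function(x, ...) {
  cat("<putatex_cohort> ", length(x$subjects), " subjects (seed ",
      x$seed, ")\n", sep = "")
  print(table(vapply(x$subjects, `[[`, "", "group"),
              vapply(x$subjects, `[[`, "", "sex")))
  invisible(x)
}

#' Extract the feature table for a whole cohort
#'
#' One row per subject x side: demographics plus the 14 texture features of
#' [compute_feature_set()].
#'
#' @param cohort A `putatex_cohort`.
#' @return Tibble with `2 * n_subjects` rows (the FeatureTable contract:
#'   complete cases, fixed column set).
#' @export
cohort_feature_table <- function(cohort) {
  stopifnot(inherits(cohort, "putatex_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    do.call(rbind, lapply(SIDES, function(sd) {
      roi <- if (sd == "left") s$roi_left else s$roi_right
      cbind(tibble::tibble(subject_id = s$subject_id, group = s$group,
                           sex = s$sex, age = s$age, side = sd),
            compute_feature_set(roi))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
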