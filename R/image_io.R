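# Raster, manifest and feature-table I/O.
#
# Dialect: 16-bit grayscale TIFF for intensity images, 8-bit {0,255} TIFF
# for masks, uncompressed in both cases so identical inputs give
# byte-identical files; delimited text (CSV) for manifests, feature tables
# and results, written/read with readr so doubles round-trip exactly.

INTENSITY_SCALE <- 65535

#' Write an ROI as an image/mask raster pair
#'
#' @param roi A `putatex_roi`.
#' @param image_path Output path for the 16-bit grayscale intensity TIFF.
#' @param mask_path Output path for the 8-bit binary mask TIFF.
#' @return Invisibly, the two paths.
#' @export
write_roi_pair <- function(roi, image_path, mask_path) {
  stopifnot(inherits(roi, "putatex_roi"))
  if (max(roi$pixels) > INTENSITY_SCALE) {
    stop("intensities exceed the 16-bit storage range")
  }
  tiff::writeTIFF(roi$pixels / INTENSITY_SCALE, image_path,
                  bits.per.sample = 16, compression = "none")
  tiff::writeTIFF(roi$mask * 1, mask_path,
                  bits.per.sample = 8, compression = "none")
  invisible(c(image = image_path, mask = mask_path))
}

#' Read an image/mask raster pair back into an ROI
#'
#' @param image_path 16-bit grayscale raster of intensities.
#' @param mask_path Same-shape binary raster; any non-zero pixel is inside.
#' @param side,pixel_spacing Passed through to [roi_image()].
#' @return A `putatex_roi` with integer intensities.
#' @export
read_roi_pair <- function(image_path, mask_path, side = "left",
                          pixel_spacing = 0.9) {
  for (p in c(image_path, mask_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- tiff::readTIFF(image_path, as.is = TRUE)
  msk <- tiff::readTIFF(mask_path, as.is = TRUE)
  if (length(dim(img)) != 2L || length(dim(msk)) != 2L) {
    stop("expected single-channel grayscale rasters")
  }
  if (!identical(dim(img), dim(msk))) {
    stop("image is ", paste(dim(img), collapse = "x"),
         " but mask is ", paste(dim(msk), collapse = "x"))
  }
  roi_image(img, msk > 0, side = side, pixel_spacing = pixel_spacing)
}

#' Write a cohort to disk: rasters plus manifest
#'
#' @param cohort A `putatex_cohort`.
#' @param out_dir Output directory (created if needed); rasters go under
#'   `out_dir/images/`, the manifest to `out_dir/manifest.csv`.
#' @return The cohort with its manifest paths filled in, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "putatex_cohort"))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    s <- cohort$subjects[[m$subject_id[i]]]
    roi <- if (m$side[i] == "left") s$roi_left else s$roi_right
    ip <- file.path(img_dir, paste0(m$subject_id[i], "_", m$side[i], ".tif"))
    mp <- file.path(img_dir, paste0(m$subject_id[i], "_", m$side[i],
                                    "_mask.tif"))
    write_roi_pair(roi, ip, mp)
    m$image_path[i] <- ip
    m$mask_path[i] <- mp
  }
  cohort$manifest <- m
  readr::write_csv(m, file.path(out_dir, "manifest.csv"), progress = FALSE)
  invisible(cohort)
}

#' Read and validate a cohort manifest
#'
#' Fails atomically: duplicate (subject_id, side) pairs or any referenced
#' file missing on disk rejects the whole manifest.
#'
#' @param path Path to `manifest.csv`.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "group", "sex", "age", "side",
              "image_path", "mask_path")
  missing <- setdiff(needed, names(m))
  if (length(missing)) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(m$subject_id, m$side)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, side) in manifest: ",
         key[duplicated(key)][1])
  }
  for (p in c(m$image_path, m$mask_path)) {
    if (is.na(p) || !file.exists(p)) {
      stop("manifest references a missing file: ", p)
    }
  }
  m
}

#' Extract the feature table for every ROI listed in a manifest
#'
#' @param manifest Manifest tibble (or path to one).
#' @return FeatureTable tibble, one row per subject x side.
#' @export
extract_features_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    roi <- read_roi_pair(manifest$image_path[i], manifest$mask_path[i],
                         side = manifest$side[i])
    cbind(tibble::tibble(subject_id = manifest$subject_id[i],
                         group = manifest$group[i], sex = manifest$sex[i],
                         age = manifest$age[i], side = manifest$side[i]),
          compute_feature_set(roi))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

feature_table_columns <- function() {
  c("subject_id", "group", "sex", "age", "side", texture_feature_names())
}

validate_feature_table <- function(features) {
  features <- tibble::as_tibble(features)
  missing <- setdiff(feature_table_columns(), names(features))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in feature_table_columns()) {
    bad <- which(is.na(features[[col]]))
    if (length(bad)) {
      stop("feature table has a missing cell at row ", bad[1],
           ", column '", col, "' (complete cases only)")
    }
  }
  features
}

#' Write / read a feature table as delimited text
#'
#' Round-trips all numeric values exactly (shortest round-trip decimal
#' representation). Incomplete rows are rejected, naming the first missing
#' row/column.
#'
#' @param features FeatureTable tibble.
#' @param path CSV path.
#' @return `write_feature_table` returns the path invisibly;
#'   `read_feature_table` returns the validated tibble.
#' @export
write_feature_table <- function(features, path) {
  features <- validate_feature_table(features)
  out <- features
  for (col in names(out)) {
    # 17 significant digits: exact round trip for doubles
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  # base read.csv: correctly-rounded double parsing for the exact round trip
  validate_feature_table(tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE)))
}
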