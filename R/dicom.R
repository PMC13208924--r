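# Minimal single-frame DICOM slice reader.
#
# Supports uncompressed little-endian transfer syntaxes (implicit VR
# 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1), MONOCHROME
# 8/16-bit pixel data, and the rescale slope/intercept transform.
# Multi-frame, encapsulated/compressed and big-endian files are rejected
# with an explicit unsupported-feature error.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

read_u32 <- function(bytes, pos) {
  # returns NA for the undefined-length marker 0xFFFFFFFF
  v <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4, endian = "little")
  if (v == -1L) NA_integer_ else v
}

LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UT", "UN", "UC", "UR")

# parse one element at pos; returns list(group, element, vr, length,
# value_pos, next_pos)
parse_element <- function(bytes, pos, explicit) {
  group <- read_u16(bytes, pos)
  element <- read_u16(bytes, pos + 2L)
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8L)
      value_pos <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      value_pos <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- read_u32(bytes, pos + 4L)
    value_pos <- pos + 8L
  }
  if (is.na(len)) {
    stop("unsupported DICOM feature: undefined-length element at tag (",
         sprintf("%04X,%04X", group, element),
         ") (sequences/encapsulated pixel data are not supported)")
  }
  list(group = group, element = element, vr = vr, length = len,
       value_pos = value_pos, next_pos = value_pos + len)
}

element_string <- function(bytes, el) {
  if (el$length == 0L) return("")
  trimws(rawToChar(bytes[el$value_pos:(el$value_pos + el$length - 1L)]),
         whitespace = "[ \t\r\n\\0]")
}

#' Read a single-frame medical-image (DICOM) slice
#'
#' Returns the stored pixel values as an integer matrix in row-major
#' orientation (first image row = first matrix row), with the rescale
#' slope/intercept transform applied and rounded to integers when
#' `window = "rescale"` (the default) and the file carries those elements.
#'
#' @param path Path to an uncompressed little-endian single-frame DICOM
#'   file.
#' @param window `"rescale"` (apply slope/intercept, then round) or
#'   `"none"` (raw stored values).
#' @return Integer matrix of pixel values.
#' @export
read_medical_slice <- function(path, window = c("rescale", "none")) {
  window <- match.arg(window)
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop("unreadable format: ", path, " is not a DICOM part-10 file ",
         "(missing DICM magic)")
  }
  # file meta group (0002,xxxx) is always explicit VR little endian
  pos <- 133L
  transfer_syntax <- TS_EXPLICIT_LE
  while (pos + 7L <= length(bytes) && read_u16(bytes, pos) == 0x0002L) {
    el <- parse_element(bytes, pos, explicit = TRUE)
    if (el$element == 0x0010L) transfer_syntax <- element_string(bytes, el)
    pos <- el$next_pos
  }
  if (!transfer_syntax %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE)) {
    stop("unsupported DICOM feature: transfer syntax ", transfer_syntax,
         " (only uncompressed little-endian files are supported)")
  }
  explicit <- transfer_syntax == TS_EXPLICIT_LE

  rows <- cols <- NA_integer_
  bits_allocated <- 16L
  pixel_representation <- 0L
  slope <- 1
  intercept <- 0
  n_frames <- 1L
  pixel_el <- NULL
  while (pos + 7L <= length(bytes)) {
    el <- parse_element(bytes, pos, explicit)
    if (el$group == 0x0028L) {
      if (el$element == 0x0010L) rows <- read_u16(bytes, el$value_pos)
      if (el$element == 0x0011L) cols <- read_u16(bytes, el$value_pos)
      if (el$element == 0x0100L) bits_allocated <- read_u16(bytes, el$value_pos)
      if (el$element == 0x0103L) {
        pixel_representation <- read_u16(bytes, el$value_pos)
      }
      if (el$element == 0x0008L) {
        n_frames <- as.integer(element_string(bytes, el))
      }
      if (el$element == 0x1052L) {
        intercept <- as.numeric(element_string(bytes, el))
      }
      if (el$element == 0x1053L) slope <- as.numeric(element_string(bytes, el))
    }
    if (el$group == 0x7FE0L && el$element == 0x0010L) pixel_el <- el
    pos <- el$next_pos
  }
  if (n_frames > 1L) {
    stop("unsupported DICOM feature: multi-frame file (", n_frames, " frames)")
  }
  if (is.null(pixel_el)) {
    stop("unreadable format: DICOM file has no pixel data element (7FE0,0010)")
  }
  if (is.na(rows) || is.na(cols)) {
    stop("unreadable format: DICOM file lacks Rows/Columns")
  }
  if (!bits_allocated %in% c(8L, 16L)) {
    stop("unsupported DICOM feature: ", bits_allocated, " bits allocated")
  }
  n_px <- rows * cols
  bytes_per <- bits_allocated %/% 8L
  if (pixel_el$length < n_px * bytes_per) {
    stop("unreadable format: pixel data (", pixel_el$length,
         " bytes) shorter than Rows x Columns requires")
  }
  raw_px <- bytes[pixel_el$value_pos:(pixel_el$value_pos +
                                        n_px * bytes_per - 1L)]
  vals <- readBin(raw_px, "integer", n = n_px, size = bytes_per,
                  signed = pixel_representation == 1L, endian = "little")
  if (bytes_per == 1L && pixel_representation == 0L) {
    vals <- as.integer(vals) %% 256L
  }
  if (window == "rescale") vals <- as.integer(round(slope * vals + intercept))
  matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
}
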