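# Minimal DICOM writer used only to build test fixtures, assembled
# byte-by-byte from the part-10 encoding rules (independent of the
# package's reader).

r_u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))
r_u32 <- function(x) {
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L), bitwShiftR(x, 24L)))
}
r_tag <- function(group, element) c(r_u16(group), r_u16(element))

pad_even <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

el_explicit_short <- function(group, element, vr, value) {
  c(r_tag(group, element), charToRaw(vr), r_u16(length(value)), value)
}
el_explicit_long <- function(group, element, vr, value) {
  c(r_tag(group, element), charToRaw(vr), as.raw(c(0, 0)),
    r_u32(length(value)), value)
}
el_implicit <- function(group, element, value) {
  c(r_tag(group, element), r_u32(length(value)), value)
}

pixel_bytes <- function(pixels) {
  writeBin(as.integer(as.vector(t(pixels))), raw(), size = 2,
           endian = "little")
}

# Write a single-frame grayscale DICOM file for tests.
write_test_dicom <- function(path, pixels, slope = NULL, intercept = NULL,
                             transfer = c("explicit", "implicit"),
                             transfer_uid = NULL,
                             n_frames = NULL, include_pixels = TRUE) {
  transfer <- match.arg(transfer)
  uid <- transfer_uid %||% if (transfer == "explicit")
    "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- el_explicit_short(0x0002L, 0x0010L, "UI", pad_even(uid, as.raw(0)))
  if (transfer == "explicit") {
    el_us <- function(g, e, v) el_explicit_short(g, e, "US", r_u16(v))
    el_str <- function(g, e, vr, s) el_explicit_short(g, e, vr, pad_even(s))
    el_px <- function(v) el_explicit_long(0x7FE0L, 0x0010L, "OW", v)
  } else {
    el_us <- function(g, e, v) el_implicit(g, e, r_u16(v))
    el_str <- function(g, e, vr, s) el_implicit(g, e, pad_even(s))
    el_px <- function(v) el_implicit(0x7FE0L, 0x0010L, v)
  }
  body <- c(
    if (!is.null(n_frames)) el_str(0x0028L, 0x0008L, "IS",
                                   as.character(n_frames)),
    el_us(0x0028L, 0x0010L, nrow(pixels)),
    el_us(0x0028L, 0x0011L, ncol(pixels)),
    el_us(0x0028L, 0x0100L, 16L),
    el_us(0x0028L, 0x0103L, 0L),
    if (!is.null(intercept)) el_str(0x0028L, 0x1052L, "DS",
                                    as.character(intercept)),
    if (!is.null(slope)) el_str(0x0028L, 0x1053L, "DS", as.character(slope)),
    if (include_pixels) el_px(pixel_bytes(pixels))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
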