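# Shared fixtures: small phantoms and a minimal DICOM writer used to exercise
# the reader (explicit-VR little endian, the tags a CT slice carries).

small_phantom <- function(true_mls = 5, seed = 1, n_slices = 8L,
                          image_size = 128L, render = TRUE, ...) {
  generate_phantom(
    phantom_spec(image_size = image_size, n_slices = n_slices,
                 true_mls_mm = true_mls, seed = seed, ...),
    render_voxels = render)
}

# anatomically plausible random keypoint set: falx roughly along the y axis
# (within ~15 degrees), septum near the falx midline
random_keypoint_set <- function(size = 512) {
  ctr <- size / 2 + stats::runif(2, -0.05, 0.05) * size
  len <- stats::runif(1, 0.4, 0.7) * size
  ang <- stats::runif(1, -15, 15) * pi / 180
  d <- c(sin(ang), cos(ang)) * len / 2
  fa <- ctr - d
  fp <- ctr + d
  sh <- stats::runif(1, -0.05, 0.05) * size
  sl <- stats::runif(1, 0.05, 0.15) * size
  keypoint_set(fa, fp,
               c(ctr[1] + sh, ctr[2] - sl / 2),
               c(ctr[1] + sh, ctr[2] + sl / 2))
}

## ---- minimal DICOM writer (test fixture only) ----

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) bytes <- c(bytes, pad)
  bytes
}

# explicit-VR element with short (2-byte) length
.dcm_el <- function(group, elem, vr, value) {
  bytes <- if (is.raw(value)) value else .dcm_pad(charToRaw(as.character(value)))
  c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr),
    .dcm_u16(length(bytes)), bytes)
}

# explicit-VR element with long (reserved + 4-byte) length (OW etc.)
.dcm_el_long <- function(group, elem, vr, bytes) {
  c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
    .dcm_u32(length(bytes)), bytes)
}

# Write one CT slice as explicit-VR little-endian DICOM. `pixels` is the HU
# matrix (rows x cols); stored values are HU - intercept (slope 1).
write_test_dicom <- function(path, pixels, z = 0,
                             pixel_spacing = c(0.5, 0.5),
                             intercept = -1024, slope = 1,
                             series_uid = "1.2.3.4", patient_id = "P1",
                             instance = 1L) {
  stored <- round((pixels - intercept) / slope)
  stopifnot(all(stored >= 0 & stored < 32768))
  rows <- nrow(pixels); cols <- ncol(pixels)
  # PixelData is row-major: write the transpose column-major
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  ds <- function(v) paste(format(v, trim = TRUE, scientific = FALSE),
                          collapse = "\\")
  out <- c(
    raw(128), charToRaw("DICM"),
    .dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dcm_el(0x0008, 0x0060, "CS", "CT"),
    .dcm_el(0x0010, 0x0020, "LO", patient_id),
    .dcm_el(0x0020, 0x000E, "UI", series_uid),
    .dcm_el(0x0020, 0x0013, "IS", as.character(instance)),
    .dcm_el(0x0020, 0x0032, "DS", ds(c(0, 0, z))),
    .dcm_el(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_el(0x0028, 0x0010, "US", .dcm_u16(rows)),
    .dcm_el(0x0028, 0x0011, "US", .dcm_u16(cols)),
    .dcm_el(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    .dcm_el(0x0018, 0x0050, "DS", "5"),
    .dcm_el(0x0028, 0x0100, "US", .dcm_u16(16)),
    .dcm_el(0x0028, 0x0103, "US", .dcm_u16(0)),
    .dcm_el(0x0028, 0x1052, "DS", ds(intercept)),
    .dcm_el(0x0028, 0x1053, "DS", ds(slope)),
    .dcm_el_long(0x7FE0, 0x0010, "OW", pix_raw))
  writeBin(out, path)
  invisible(path)
}

# a 3-slice DICOM series directory; slice i has constant HU = hu_values[i]
write_test_series <- function(dir, hu_values = c(0, 30, 60),
                              shape = c(16, 20), pixel_spacing = c(0.5, 0.6),
                              z = c(0, 5, 10), shuffle = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- if (shuffle) rev(seq_along(hu_values)) else seq_along(hu_values)
  for (i in ord) {
    px <- matrix(hu_values[i], shape[1], shape[2])
    px[1, 1] <- hu_values[i] + i  # asymmetric marker
    write_test_dicom(file.path(dir, sprintf("im%02d.dcm", i)), px,
                     z = z[i], pixel_spacing = pixel_spacing,
                     instance = i)
  }
  invisible(dir)
}
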