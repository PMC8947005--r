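# Reading CT volumes (DICOM series / NIfTI), keypoint annotations (JSON) and
# writing MLS results (CSV / JSON).
#
# The DICOM reader is a minimal pure-R parser for uncompressed little-endian
# series (explicit and implicit VR), covering the geometry, rescale and pixel
# tags a CT volume needs. Compressed or big-endian transfer syntaxes are
# rejected with a clear error.

#' Construct a CT volume
#'
#' @param voxels 3-D array of Hounsfield units, indexed `(slice, row, col)`,
#'   slices in ascending axial position.
#' @param spacing `(slice_mm, row_mm, col_mm)`, all strictly positive.
#' @param scan_id,patient_id identifiers.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, scan_id = "scan", patient_id = "patient") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array (slice, row, col)", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (slice, row, col) in mm",
         call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("voxels contain non-finite HU values", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 scan_id = scan_id, patient_id = patient_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s (patient %s): %d slices of %dx%d px, spacing %.3f/%.3f/%.3f mm, HU [%.0f, %.0f]\n",
              x$scan_id, x$patient_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Load a CT volume from disk
#'
#' @param path a DICOM series directory (one scan) or a NIfTI file
#'   (`.nii` / `.nii.gz`).
#' @param format_hint `"auto"` (directory = DICOM, file = NIfTI),
#'   `"dicom"` or `"nifti"`.
#' @param scan_id,patient_id override the identifiers read from metadata.
#' @return a [ct_volume()] in HU with slices in ascending axial position.
#' @export
load_ct_volume <- function(path, format_hint = c("auto", "dicom", "nifti"),
                           scan_id = NULL, patient_id = NULL) {
  format_hint <- match.arg(format_hint)
  fmt <- switch(format_hint,
                auto = if (dir.exists(path)) "dicom" else "nifti",
                format_hint)
  vol <- if (fmt == "dicom") .load_dicom_series(path) else .load_nifti(path)
  if (!is.null(scan_id)) vol$scan_id <- scan_id
  if (!is.null(patient_id)) vol$patient_id <- patient_id
  vol
}

#' Write a CT volume as NIfTI
#'
#' The voxel array and spacing round-trip exactly through
#' [load_ct_volume()] (HU stored as float64).
#'
#' @param vol a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  # NIfTI axis order (x, y, z) = (col, row, slice)
  arr <- aperm(vol$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$spacing[3], vol$spacing[2], vol$spacing[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

.load_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("missing or invalid voxel spacing (pixdim) in NIfTI header",
         call. = FALSE)
  sid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = c(pd[3], pd[2], pd[1]),
            scan_id = sid, patient_id = sid)
}

## ---- minimal DICOM parsing ------------------------------------------------

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

.EXPLICIT_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list of elements keyed "GGGG,EEEE".
.parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  elems <- list()
  explicit <- TRUE  # file meta group is always explicit little endian
  ts <- NULL
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- .u16(raw[pos:(pos + 1L)])
    elem <- .u16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (group != 2L && !is.null(ts) && !ts$seen) {
      explicit <- ts$explicit
      ts$seen <- TRUE
    }
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .EXPLICIT_LONG_VRS) {
        len <- .u32(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .u16(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw[(pos):(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM element (sequences unsupported): ",
           sprintf("%04X,%04X", group, elem), call. = FALSE)
    val <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, elem)
    elems[[key]] <- list(vr = vr, bytes = val)
    if (key == "0002,0010") {
      uid <- trimws(rawToChar(val[val != as.raw(0)]))
      if (uid == "1.2.840.10008.1.2")
        ts <- list(explicit = FALSE, seen = FALSE)
      else if (uid == "1.2.840.10008.1.2.1")
        ts <- list(explicit = TRUE, seen = FALSE)
      else
        stop("unsupported DICOM transfer syntax: ", uid,
             " (only uncompressed little endian is supported)", call. = FALSE)
    }
  }
  elems
}

.dcm_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$bytes[e$bytes != as.raw(0)]))
}

.dcm_num <- function(elems, key) {
  s <- .dcm_str(elems, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  .u16(e$bytes[1:2])
}

.read_dicom_slice <- function(path) {
  el <- .parse_dicom(path)
  rows <- .dcm_us(el, "0028,0010")
  cols <- .dcm_us(el, "0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM missing Rows/Columns: ", path, call. = FALSE)
  ps <- .dcm_num(el, "0028,0030")
  if (is.null(ps) || length(ps) != 2L)
    stop("DICOM missing PixelSpacing (0028,0030): ", path, call. = FALSE)
  bits <- .dcm_us(el, "0028,0100")
  if (is.null(bits) || bits != 16L)
    stop("only 16-bit DICOM pixel data is supported: ", path, call. = FALSE)
  signed <- isTRUE(.dcm_us(el, "0028,0103") == 1L)
  pd <- el[["7FE0,0010"]]
  if (is.null(pd)) stop("DICOM missing PixelData: ", path, call. = FALSE)
  stored <- readBin(pd$bytes, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  slope <- .dcm_num(el, "0028,1053")
  intercept <- .dcm_num(el, "0028,1052")
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  # PixelData is row-major (first row left to right)
  px <- t(matrix(stored * slope + intercept, nrow = cols, ncol = rows))
  list(pixels = px,
       pixel_spacing = ps,                        # (row_mm, col_mm)
       ipp = .dcm_num(el, "0020,0032"),           # ImagePositionPatient
       iop = .dcm_num(el, "0020,0037"),           # ImageOrientationPatient
       instance = .dcm_num(el, "0020,0013"),
       thickness = .dcm_num(el, "0018,0050"),
       series_uid = .dcm_str(el, "0020,000E"),
       patient_id = .dcm_str(el, "0010,0020"))
}

.load_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, .read_dicom_slice)

  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed slice shapes in DICOM series: ", paste(unique(shapes), collapse = ", "),
         call. = FALSE)
  ps <- slices[[1]]$pixel_spacing
  iops <- lapply(slices, `[[`, "iop")
  have_iop <- !vapply(iops, is.null, TRUE)
  if (any(have_iop)) {
    ref <- iops[which(have_iop)[1]][[1]]
    for (o in iops[have_iop])
      if (max(abs(o - ref)) > 1e-4)
        stop("mixed slice orientations in DICOM series", call. = FALSE)
    normal <- c(ref[2] * ref[6] - ref[3] * ref[5],
                ref[3] * ref[4] - ref[1] * ref[6],
                ref[1] * ref[5] - ref[2] * ref[4])
  } else normal <- c(0, 0, 1)

  pos <- vapply(slices, function(s) {
    if (!is.null(s$ipp)) sum(s$ipp * normal)
    else if (!is.null(s$instance)) s$instance
    else NA_real_
  }, 0)
  if (any(is.na(pos)))
    stop("DICOM missing ImagePositionPatient (0020,0032) and InstanceNumber; ",
         "cannot order slices", call. = FALSE)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]

  if (length(slices) >= 2L) {
    gaps <- diff(pos)
    if (any(gaps <= 0)) stop("duplicate slice positions in DICOM series", call. = FALSE)
    slice_mm <- stats::median(gaps)
  } else {
    slice_mm <- slices[[1]]$thickness
    if (is.null(slice_mm))
      stop("single-slice series missing SliceThickness (0018,0050); ",
           "cannot determine slice spacing", call. = FALSE)
  }

  d <- dim(slices[[1]]$pixels)
  vox <- array(0, dim = c(length(slices), d[1], d[2]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$pixels
  sid <- slices[[1]]$series_uid
  pid <- slices[[1]]$patient_id
  ct_volume(vox, spacing = c(slice_mm, ps[1], ps[2]),
            scan_id = if (is.null(sid)) basename(dir) else sid,
            patient_id = if (is.null(pid)) basename(dir) else pid)
}

## ---- keypoint annotations -------------------------------------------------

#' Load keypoint annotations from JSON
#'
#' Schema: an array of records
#' `{"scan_id": str, "slice_index": int, "annotator": str,
#'   "keypoints": {"falx_anterior": [x,y], ...}}` with exactly the four legal
#' keypoint names. Annotation may be sparse: not every slice of a scan need
#' carry a record.
#'
#' @param path JSON file.
#' @param volume optional [ct_volume()]; when supplied, records for its
#'   `scan_id` are validated against slice count and image bounds.
#' @return list of `annotation_record` objects (order preserved).
#' @export
load_annotations <- function(path, volume = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- vector("list", length(recs))
  seen <- character(0)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    need <- c("scan_id", "slice_index", "annotator", "keypoints")
    if (!all(need %in% names(r)))
      stop("annotation record ", i, " missing field(s): ",
           paste(setdiff(need, names(r)), collapse = ", "), call. = FALSE)
    bad <- setdiff(names(r$keypoints), KEYPOINT_NAMES)
    if (length(bad))
      stop("unknown keypoint name(s) ", paste(sQuote(bad), collapse = ", "),
           "; legal names are: ", paste(KEYPOINT_NAMES, collapse = ", "),
           call. = FALSE)
    if (!all(KEYPOINT_NAMES %in% names(r$keypoints)))
      stop("annotation record ", i, " missing keypoint(s): ",
           paste(setdiff(KEYPOINT_NAMES, names(r$keypoints)), collapse = ", "),
           call. = FALSE)
    key <- paste(r$scan_id, r$slice_index, r$annotator, sep = "\r")
    if (key %in% seen)
      stop("duplicate annotation for (", r$scan_id, ", slice ", r$slice_index,
           ", ", r$annotator, ")", call. = FALSE)
    seen <- c(seen, key)
    kp <- keypoint_set(unlist(r$keypoints$falx_anterior),
                       unlist(r$keypoints$falx_posterior),
                       unlist(r$keypoints$septum_anterior),
                       unlist(r$keypoints$septum_posterior))
    rec <- annotation_record(r$scan_id, r$slice_index, kp, r$annotator)
    if (!is.null(volume) && identical(volume$scan_id, rec$scan_id))
      .check_record_bounds(rec, volume)
    out[[i]] <- rec
  }
  out
}

#' Construct an annotation record
#' @param scan_id scan identifier.
#' @param slice_index 0-based axial slice index.
#' @param keypoints a [keypoint_set()].
#' @param annotator annotator identifier.
#' @return an object of class `annotation_record`.
#' @export
annotation_record <- function(scan_id, slice_index, keypoints,
                              annotator = "unknown") {
  stopifnot(inherits(keypoints, "keypoint_set"))
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0)
    stop("slice_index must be a non-negative integer", call. = FALSE)
  structure(list(scan_id = scan_id, slice_index = slice_index,
                 annotator = annotator, keypoints = keypoints),
            class = "annotation_record")
}

.check_record_bounds <- function(rec, volume) {
  d <- dim(volume$voxels)
  if (rec$slice_index >= d[1])
    stop("slice_index ", rec$slice_index, " outside scan ", rec$scan_id,
         " (", d[1], " slices)", call. = FALSE)
  for (nm in KEYPOINT_NAMES) {
    p <- rec$keypoints[[nm]]
    if (p[1] > d[3] - 1 || p[2] > d[2] - 1)
      stop("keypoint ", nm, " outside image bounds for scan ", rec$scan_id,
           call. = FALSE)
  }
  invisible(rec)
}

#' Save annotation records as JSON
#' @param records list of `annotation_record`s.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(records, path) {
  objs <- lapply(records, function(r) {
    list(scan_id = r$scan_id, slice_index = r$slice_index,
         annotator = r$annotator,
         keypoints = lapply(unclass(r$keypoints)[KEYPOINT_NAMES], as.numeric))
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- MLS results ----------------------------------------------------------

#' Write per-scan MLS results
#'
#' CSV columns: `scan_id, slice_index_of_max, mls_mm, n_slices_detected,
#' per_slice` where `per_slice` packs `index:value` pairs separated by `|`
#' (6-decimal precision) so the file reads back losslessly to that precision.
#' The JSON format mirrors the full [aggregate_scan()] structure.
#'
#' @param results list of `mls_result`s.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(
      scan_id = vapply(results, function(r) as.character(r$scan_id), ""),
      slice_index_of_max = vapply(results, function(r)
        if (r$defined) r$argmax_slice_index else NA_integer_, 0L),
      mls_mm = vapply(results, function(r)
        if (r$defined) round(r$scan_mls_mm, 6) else NA_real_, 0),
      n_slices_detected = vapply(results, function(r) nrow(r$per_slice), 0L),
      per_slice = vapply(results, function(r)
        paste(sprintf("%d:%.6f", r$per_slice$slice_index, r$per_slice$mls_mm),
              collapse = "|"), ""),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    objs <- lapply(results, function(r)
      list(scan_id = r$scan_id, slice_index_of_max = r$argmax_slice_index,
           mls_mm = r$scan_mls_mm, n_slices_detected = nrow(r$per_slice),
           source = r$source, defined = r$defined,
           per_slice = list(slice_index = r$per_slice$slice_index,
                            mls_mm = r$per_slice$mls_mm)))
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back per-scan MLS results
#' @param path file written by [write_results()].
#' @param format `"csv"` or `"json"`.
#' @param source provenance to stamp on the results (CSV does not store it).
#' @return list of `mls_result`s.
#' @export
read_results <- function(path, format = c("csv", "json"),
                         source = "prediction") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(scan_id = "character",
                                         per_slice = "character"))
    lapply(seq_len(nrow(df)), function(i) {
      ps <- df$per_slice[i]
      per_slice <- if (is.na(ps) || !nzchar(ps))
        data.frame(slice_index = integer(), mls_mm = numeric())
      else {
        parts <- strsplit(strsplit(ps, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
        data.frame(slice_index = as.integer(vapply(parts, `[`, "", 1)),
                   mls_mm = as.numeric(vapply(parts, `[`, "", 2)))
      }
      aggregate_scan(per_slice, df$scan_id[i], source)
    })
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(objs, function(o) {
      per_slice <- data.frame(
        slice_index = vapply(o$per_slice$slice_index, as.integer, 0L),
        mls_mm = vapply(o$per_slice$mls_mm, as.numeric, 0))
      aggregate_scan(per_slice, o$scan_id,
                     if (is.null(o$source)) source else o$source)
    })
  }
}
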