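# Keypoint data model and midline-shift geometry.
#
# Conventions (shared by the whole package):
#   * pixel coordinates are 0-based, x = column index, y = row index,
#     origin at the top-left of the axial image;
#   * spacing vectors are (row_mm, col_mm): y displacements are scaled by
#     row_mm, x displacements by col_mm;
#   * MLS is reported unsigned (laterality is not encoded).

KEYPOINT_NAMES <- c("falx_anterior", "falx_posterior",
                    "septum_anterior", "septum_posterior")

#' Construct a keypoint set for one axial slice
#'
#' The four landmarks that define the keypoint-based midline shift: the
#' anterior and posterior ends of the falx (whose connecting line is the ideal
#' midline) and the anterior and posterior ends of the septum pellucidum
#' (whose displacement from that line is the shift).
#'
#' @param falx_anterior,falx_posterior,septum_anterior,septum_posterior
#'   numeric `(x, y)` pairs in 0-based pixel coordinates (x = column,
#'   y = row, origin top-left).
#' @return an object of class `keypoint_set`: a named list of the four
#'   `(x, y)` pairs.
#' @examples
#' k <- keypoint_set(c(256, 100), c(256, 400), c(262, 240), c(262, 260))
#' compute_mls_slice(k, spacing = c(0.5, 0.5))
#' @export
keypoint_set <- function(falx_anterior, falx_posterior,
                         septum_anterior, septum_posterior) {
  k <- list(falx_anterior = as.numeric(falx_anterior),
            falx_posterior = as.numeric(falx_posterior),
            septum_anterior = as.numeric(septum_anterior),
            septum_posterior = as.numeric(septum_posterior))
  validate_keypoint_set(k)
  structure(k, class = "keypoint_set")
}

validate_keypoint_set <- function(k) {
  for (nm in KEYPOINT_NAMES) {
    p <- k[[nm]]
    if (length(p) != 2L || !all(is.finite(p)))
      stop("keypoint '", nm, "' must be a finite (x, y) pair", call. = FALSE)
    if (any(p < 0))
      stop("keypoint '", nm, "' has a negative coordinate", call. = FALSE)
  }
  if (all(k$falx_anterior == k$falx_posterior))
    stop("degenerate falx: falx_anterior and falx_posterior coincide",
         call. = FALSE)
  invisible(k)
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat("<keypoint_set>\n")
  for (nm in KEYPOINT_NAMES)
    cat(sprintf("  %-16s (%.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

# (x, y) pixel pair -> (x_mm, y_mm) physical pair. spacing = (row_mm, col_mm).
.kp_mm <- function(p, spacing) c(p[1] * spacing[2], p[2] * spacing[1])

#' Midline shift of one slice from its keypoints
#'
#' The midline shift is the distance in mm between the midpoint of the falx
#' line (the ideal midline) and the midpoint of the septum pellucidum
#' segment. Pixel displacements are converted to mm per axis before taking
#' the Euclidean norm, so anisotropic spacing is handled correctly.
#'
#' @param k a [keypoint_set()].
#' @param spacing numeric `(row_mm, col_mm)`, both positive.
#' @param mode `"midpoint_distance"` (default): point-to-point distance
#'   between the two midpoints. `"perpendicular_to_falx"`: distance from the
#'   septum midpoint to the infinite falx line, an alternative reading of the
#'   construction.
#' @return midline shift in mm (non-negative scalar).
#' @export
compute_mls_slice <- function(k, spacing,
                              mode = c("midpoint_distance",
                                       "perpendicular_to_falx")) {
  mode <- match.arg(mode)
  validate_keypoint_set(k)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive values (row_mm, col_mm)", call. = FALSE)
  fa <- .kp_mm(k$falx_anterior, spacing)
  fp <- .kp_mm(k$falx_posterior, spacing)
  sa <- .kp_mm(k$septum_anterior, spacing)
  sp <- .kp_mm(k$septum_posterior, spacing)
  falx_mid <- (fa + fp) / 2
  sept_mid <- (sa + sp) / 2
  if (mode == "midpoint_distance") {
    sqrt(sum((sept_mid - falx_mid)^2))
  } else {
    u <- fp - fa
    len <- sqrt(sum(u^2))
    v <- sept_mid - fa
    abs(u[1] * v[2] - u[2] * v[1]) / len
  }
}

#' Ground-truth bounding box from the falx line
#'
#' The detector's ground-truth box is built from the falx line: an
#' axis-aligned box centred on the falx midpoint whose height is 1.2 times
#' the falx length and whose width is 0.8 times that height. Because the falx
#' runs along the anterior-posterior (y) axis on an axial slice, the 1.2
#' scaling guarantees both falx endpoints fall inside the box.
#'
#' @param k a [keypoint_set()].
#' @param image_shape optional `(rows, cols)`; when supplied the box is
#'   clipped to `[0, cols-1] x [0, rows-1]` (clipping may break the 0.8
#'   aspect ratio).
#' @return an object of class `bounding_box`: a list with `x_min`, `y_min`,
#'   `x_max`, `y_max` in pixels.
#' @export
keypoints_to_bbox <- function(k, image_shape = NULL) {
  validate_keypoint_set(k)
  fa <- k$falx_anterior
  fp <- k$falx_posterior
  len <- sqrt(sum((fp - fa)^2))
  ctr <- (fa + fp) / 2
  height <- 1.2 * len
  width <- 0.8 * height
  box <- list(x_min = ctr[1] - width / 2, y_min = ctr[2] - height / 2,
              x_max = ctr[1] + width / 2, y_max = ctr[2] + height / 2)
  if (!is.null(image_shape)) {
    box$x_min <- max(box$x_min, 0)
    box$y_min <- max(box$y_min, 0)
    box$x_max <- min(box$x_max, image_shape[2] - 1)
    box$y_max <- min(box$y_max, image_shape[1] - 1)
  }
  if (box$x_min >= box$x_max || box$y_min >= box$y_max)
    stop("degenerate bounding box", call. = FALSE)
  structure(box, class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> x [%.2f, %.2f]  y [%.2f, %.2f]  (%.2f x %.2f px)\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              x$x_max - x$x_min, x$y_max - x$y_min))
  invisible(x)
}

#' Aggregate per-slice midline shifts into a per-scan result
#'
#' The scan-level MLS is the greatest per-slice MLS; its slice index is kept
#' as the representative slice. Ties break to the lowest slice index. An
#' empty input (no slice measured) yields a result with `defined = FALSE`
#' and `scan_mls_mm = NA`.
#'
#' @param per_slice data.frame with columns `slice_index` and `mls_mm`
#'   (possibly zero rows), or `NULL`.
#' @param scan_id scan identifier.
#' @param source `"annotation"` or `"prediction"`.
#' @return an object of class `mls_result`.
#' @export
aggregate_scan <- function(per_slice, scan_id,
                           source = c("annotation", "prediction")) {
  source <- match.arg(source)
  if (is.null(per_slice))
    per_slice <- data.frame(slice_index = integer(), mls_mm = numeric())
  stopifnot(is.data.frame(per_slice),
            all(c("slice_index", "mls_mm") %in% names(per_slice)))
  if (nrow(per_slice) && any(per_slice$mls_mm < 0 | !is.finite(per_slice$mls_mm)))
    stop("per-slice MLS values must be finite and non-negative", call. = FALSE)
  per_slice <- per_slice[, c("slice_index", "mls_mm")]
  if (nrow(per_slice) == 0L) {
    res <- list(scan_id = scan_id, per_slice = per_slice,
                scan_mls_mm = NA_real_, argmax_slice_index = NA_integer_,
                source = source, defined = FALSE)
  } else {
    ord <- order(per_slice$slice_index)   # tie-break: lowest slice index
    ps <- per_slice[ord, , drop = FALSE]
    i <- which.max(ps$mls_mm)
    res <- list(scan_id = scan_id, per_slice = per_slice,
                scan_mls_mm = ps$mls_mm[i],
                argmax_slice_index = as.integer(ps$slice_index[i]),
                source = source, defined = TRUE)
  }
  structure(res, class = "mls_result")
}

#' @export
print.mls_result <- function(x, ...) {
  cat("<mls_result> scan", x$scan_id, " source:", x$source, "\n")
  if (x$defined)
    cat(sprintf("  scan MLS %.3f mm at slice %d (%d slice(s) measured)\n",
                x$scan_mls_mm, x$argmax_slice_index, nrow(x$per_slice)))
  else
    cat("  undefined (no slice measured)\n")
  invisible(x)
}

#' Scan MLS from keypoint annotations
#'
#' The manual-keypoint measurement route: computes the per-slice MLS of every
#' annotation record of one scan and aggregates to the per-scan maximum.
#'
#' @param annotations list of `annotation_record`s for a single scan (one
#'   record per slice).
#' @param spacing `(row_mm, col_mm)` of the scan.
#' @param scan_id optional; defaults to the records' common scan_id.
#' @param mls_mode see [compute_mls_slice()].
#' @return an `mls_result` with `source = "annotation"`.
#' @export
mls_from_annotations <- function(annotations, spacing, scan_id = NULL,
                                 mls_mode = "midpoint_distance") {
  if (!length(annotations)) {
    if (is.null(scan_id)) stop("no annotations and no scan_id", call. = FALSE)
    return(aggregate_scan(NULL, scan_id, "annotation"))
  }
  ids <- unique(vapply(annotations, function(a) as.character(a$scan_id), ""))
  if (is.null(scan_id)) {
    if (length(ids) > 1)
      stop("annotations span several scans (", paste(ids, collapse = ", "),
           "); supply scan_id", call. = FALSE)
    scan_id <- ids
  } else {
    annotations <- Filter(function(a) identical(as.character(a$scan_id),
                                                as.character(scan_id)),
                          annotations)
  }
  per_slice <- do.call(rbind, lapply(annotations, function(a)
    data.frame(slice_index = a$slice_index,
               mls_mm = compute_mls_slice(a$keypoints, spacing,
                                          mode = mls_mode))))
  aggregate_scan(per_slice, scan_id, "annotation")
}

#' Rescale keypoints between image resolutions
#'
#' Coordinates are scaled per axis by `to/from`, keeping annotations
#' consistent across the 512x512 resize. Inverse of itself up to rounding.
#'
#' @param k a [keypoint_set()].
#' @param from_shape,to_shape `(rows, cols)` of the source and target images
#'   (a scalar is recycled to square).
#' @return a rescaled `keypoint_set`.
#' @export
rescale_keypoints <- function(k, from_shape, to_shape) {
  if (length(from_shape) == 1L) from_shape <- rep(from_shape, 2L)
  if (length(to_shape) == 1L) to_shape <- rep(to_shape, 2L)
  stopifnot(all(from_shape > 0), all(to_shape > 0))
  sx <- to_shape[2] / from_shape[2]
  sy <- to_shape[1] / from_shape[1]
  out <- lapply(unclass(k)[KEYPOINT_NAMES],
                function(p) c(p[1] * sx, p[2] * sy))
  structure(out, class = "keypoint_set")
}
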