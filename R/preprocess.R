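# CT preprocessing: Hounsfield windowing, adjacent-slice stacking and
# bilinear resize to the model's 512x512 input, normalised to (0, 1).

#' Default CT windows
#'
#' The three `(level, width)` Hounsfield windows applied to the three
#' adjacent-slice channels: a subdural-type window (80, 200), a soft-tissue
#' window (40, 380) and a bone window (600, 2800).
#' @return list of three `window_spec` objects.
#' @export
default_windows <- function() {
  list(window_spec(80, 200), window_spec(40, 380), window_spec(600, 2800))
}

#' CT display window
#' @param level window level (centre) in HU.
#' @param width window width in HU, strictly positive.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(level, width) {
  if (!is.finite(level) || !is.finite(width) || width <= 0)
    stop("window width must be positive and level finite", call. = FALSE)
  structure(list(level = level, width = width), class = "window_spec")
}

#' Apply a Hounsfield window to a slice
#'
#' Maps `[level - width/2, level + width/2]` linearly onto `[0, 1]` and clips
#' outside that range; a total function on finite HU input.
#'
#' @param slice_hu 2-D matrix of HU values.
#' @param w a [window_spec()].
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
apply_window <- function(slice_hu, w) {
  stopifnot(inherits(w, "window_spec"))
  if (any(!is.finite(slice_hu)))
    stop("non-finite HU values in input slice", call. = FALSE)
  lo <- w$level - w$width / 2
  out <- (slice_hu - lo) / w$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Stack the three spatially adjacent slices around slice i
#'
#' Returns raw HU channels `(i-1, i, i+1)`; at the volume boundaries the edge
#' slice is replicated so the function is total over valid indices.
#'
#' @param vol a [ct_volume()].
#' @param i 0-based slice index.
#' @return list of three HU matrices (below, centre, above).
#' @export
stack_slices <- function(vol, i) {
  n <- dim(vol$voxels)[1]
  if (i < 0 || i >= n)
    stop("slice index ", i, " out of range [0, ", n - 1, "]", call. = FALSE)
  idx <- pmin(pmax(c(i - 1, i, i + 1), 0), n - 1) + 1L  # 1-based, edge-replicated
  lapply(idx, function(j) vol$voxels[j, , ])
}

#' Bilinear resize of one slice
#'
#' Resizes to `target x target` pixels with bilinear interpolation and
#' rescales the pixel spacing so the physical field of view is preserved:
#' `effective_spacing = native_spacing * native_size / target` per axis.
#'
#' @param slice 2-D matrix.
#' @param spacing native `(row_mm, col_mm)`.
#' @param target output side length in pixels (default 512).
#' @return list with `pixels` (target x target matrix) and
#'   `effective_spacing` `(row_mm, col_mm)`.
#' @export
resize_slice <- function(slice, spacing = c(1, 1), target = 512L) {
  d <- dim(slice)
  if (is.null(d) || any(d < 1))
    stop("slice must be a non-empty 2-D matrix", call. = FALSE)
  eff <- c(spacing[1] * d[1] / target, spacing[2] * d[2] / target)
  if (d[1] == target && d[2] == target)
    return(list(pixels = slice, effective_spacing = eff))
  px <- EBImage::resize(slice, w = target, h = target, filter = "bilinear")
  list(pixels = px, effective_spacing = eff)
}

#' Preprocess a CT volume into model-ready inputs
#'
#' For every slice i: the three adjacent slices `(i-1, i, i+1)` are resized to
#' `target x target`, window k is applied to adjacent-slice channel k, and the
#' result is a 3-channel image in `[0, 1]`.
#'
#' @param vol a [ct_volume()].
#' @param windows list of exactly three [window_spec()]s
#'   (default [default_windows()]).
#' @param target output side length (default 512).
#' @return list of `model_input` objects, one per slice, each with fields
#'   `pixels` (target x target x 3 array in `[0,1]`), `scan_id`,
#'   `center_slice_index` (0-based), `effective_spacing` `(row_mm, col_mm)`
#'   and `native_shape` `(rows, cols)`.
#' @export
preprocess_volume <- function(vol, windows = default_windows(), target = 512L) {
  stopifnot(inherits(vol, "ct_volume"))
  if (length(windows) != 3L || !all(vapply(windows, inherits, TRUE, "window_spec")))
    stop("windows must be a list of exactly 3 window_spec objects", call. = FALSE)
  n <- dim(vol$voxels)[1]
  native <- dim(vol$voxels)[2:3]
  sp <- vol$spacing[2:3]  # (row_mm, col_mm)
  lapply(seq_len(n) - 1L, function(i) {
    chans <- stack_slices(vol, i)
    px <- array(0, dim = c(target, target, 3L))
    eff <- NULL
    for (kk in 1:3) {
      r <- resize_slice(chans[[kk]], spacing = sp, target = target)
      px[, , kk] <- apply_window(r$pixels, windows[[kk]])
      eff <- r$effective_spacing
    }
    structure(list(pixels = px, scan_id = vol$scan_id,
                   center_slice_index = i, effective_spacing = eff,
                   native_shape = native),
              class = "model_input")
  })
}
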